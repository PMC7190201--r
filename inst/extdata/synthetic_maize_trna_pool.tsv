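anticodon	copies
AAC	22
AAG	22
AAT	22
ACC	22
ACG	22
AGA	22
AGC	22
AGG	22
AGT	22
CAA	27
CAC	27
CAG	27
CAT	27
CCA	27
CCC	27
CCG	27
CCT	27
CGA	27
CGC	27
CGG	27
CGT	27
CTC	27
CTG	27
CTT	27
GAA	31
GAC	31
GAG	31
GAT	31
GCA	31
GCC	31
GCT	31
GGA	31
GGC	31
GGG	31
GGT	31
GTA	31
GTC	31
GTG	31
GTT	31
TAA	10
TAC	10
TAG	10
TCC	10
TCG	10
TCT	10
TGA	10
TGC	10
TGG	10
TGT	10
TTC	10
TTG	10
TTT	10
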