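# synthetic illustrative tAI-style codon weights (not derived from real tRNA abundances)
TTT	0.928
CTT	1.000
ATT	0.393
GTT	0.856
TCT	0.695
CCT	1.000
ACT	0.776
GCT	0.264
TAT	1.000
CAT	1.000
AAT	1.000
GAT	0.761
TGT	1.000
CGT	0.367
AGT	0.543
GGT	0.949
TTC	1.000
CTC	0.250
ATC	1.000
GTC	0.626
TCC	1.000
CCC	0.268
ACC	1.000
GCC	1.000
TAC	0.220
CAC	0.587
AAC	0.482
GAC	1.000
TGC	0.530
CGC	0.861
AGC	0.777
GGC	0.839
TTA	0.480
CTA	0.732
ATA	0.153
GTA	1.000
TCA	0.156
CCA	0.327
ACA	0.921
GCA	0.670
CAA	1.000
AAA	0.520
GAA	0.182
CGA	1.000
AGA	0.517
GGA	1.000
TTG	0.905
CTG	0.694
ATG	1.000
GTG	0.676
TCG	0.433
CCG	0.445
ACG	0.489
GCG	0.817
CAG	0.183
AAG	1.000
GAG	1.000
TGG	1.000
CGG	0.372
AGG	0.587
GGG	0.724
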