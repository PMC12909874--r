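codon	amino_acid	frequency
GCG	A	0.36
GCC	A	0.27
GCA	A	0.21
GCT	A	0.16
CGC	R	0.40
CGT	R	0.38
CGG	R	0.10
CGA	R	0.06
AGA	R	0.04
AGG	R	0.02
AAC	N	0.55
AAT	N	0.45
GAT	D	0.63
GAC	D	0.37
TGC	C	0.55
TGT	C	0.45
CAG	Q	0.65
CAA	Q	0.35
GAA	E	0.68
GAG	E	0.32
GGC	G	0.40
GGT	G	0.34
GGG	G	0.15
GGA	G	0.11
CAT	H	0.57
CAC	H	0.43
ATT	I	0.51
ATC	I	0.42
ATA	I	0.07
CTG	L	0.50
TTA	L	0.13
TTG	L	0.13
CTT	L	0.10
CTC	L	0.10
CTA	L	0.04
AAA	K	0.76
AAG	K	0.24
ATG	M	1.00
TTT	F	0.57
TTC	F	0.43
CCG	P	0.52
CCA	P	0.19
CCT	P	0.16
CCC	P	0.13
AGC	S	0.28
TCT	S	0.15
TCC	S	0.15
TCG	S	0.15
AGT	S	0.15
TCA	S	0.12
ACC	T	0.44
ACG	T	0.27
ACT	T	0.17
ACA	T	0.13
TGG	W	1.00
TAT	Y	0.57
TAC	Y	0.43
GTG	V	0.37
GTT	V	0.26
GTC	V	0.20
GTA	V	0.15
TAA	*	0.64
TGA	*	0.29
TAG	*	0.07
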