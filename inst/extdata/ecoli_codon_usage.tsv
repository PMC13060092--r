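codon	aa	per_thousand
TTT	F	22.1
TTC	F	16.0
TTA	L	14.3
TTG	L	13.0
CTT	L	11.9
CTC	L	10.2
CTA	L	4.2
CTG	L	48.4
ATT	I	29.8
ATC	I	23.7
ATA	I	6.8
ATG	M	26.4
GTT	V	18.8
GTC	V	14.3
GTA	V	11.6
GTG	V	24.4
TCT	S	10.4
TCC	S	9.1
TCA	S	8.9
TCG	S	8.5
AGT	S	9.9
AGC	S	15.2
CCT	P	7.5
CCC	P	5.4
CCA	P	8.6
CCG	P	20.9
ACT	T	10.3
ACC	T	22.0
ACA	T	9.3
ACG	T	13.7
GCT	A	17.5
GCC	A	24.2
GCA	A	21.2
GCG	A	32.1
TAT	Y	17.5
TAC	Y	12.2
TAA	*	1.8
TAG	*	0.3
TGA	*	1.0
CAT	H	12.5
CAC	H	9.3
CAA	Q	14.6
CAG	Q	28.4
AAT	N	20.6
AAC	N	21.4
AAA	K	35.3
AAG	K	12.4
GAT	D	32.7
GAC	D	19.2
GAA	E	39.1
GAG	E	18.7
TGT	C	5.2
TGC	C	6.1
TGG	W	13.9
CGT	R	20.9
CGC	R	21.1
CGA	R	3.8
CGG	R	5.9
AGA	R	2.8
AGG	R	1.6
GGT	G	25.5
GGC	G	27.1
GGA	G	9.5
GGG	G	11.3
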