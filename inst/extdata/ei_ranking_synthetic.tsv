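# SYNTHETIC exchangeability ranking of the 75 elementary amino-acid classes.
# Generated deterministically by khscan::synthetic_ei_ranking(): classes are
# ordered by transition-weighted codon connectivity combined with hydropathy
# and residue-volume similarity. This is a stand-in, not a transcription of
# any published evolutionary index; supply your own ranking TSV (columns
# aa1, aa2, rank) to load_ei_ranking() for substantive analyses.
# provenance: synthetic
aa1	aa2	rank
P	S	1
A	T	2
A	V	3
I	V	4
L	V	5
S	T	6
L	P	7
D	N	8
P	T	9
K	R	10
F	L	11
I	L	12
G	S	13
E	K	14
H	Y	15
A	S	16
A	G	17
H	R	18
Q	R	19
I	T	20
E	Q	21
N	S	22
H	Q	23
A	P	24
D	E	25
K	Q	26
D	G	27
H	N	28
I	M	29
F	I	30
C	S	31
D	H	32
P	R	33
L	M	34
P	Q	35
H	P	36
F	V	37
M	V	38
N	T	39
E	G	40
C	Y	41
R	W	42
K	N	43
G	R	44
F	S	45
L	S	46
M	T	47
G	V	48
C	F	49
F	Y	50
N	Y	51
C	G	52
D	Y	53
K	T	54
S	Y	55
R	S	56
A	D	57
L	R	58
C	R	59
R	T	60
A	E	61
I	S	62
H	L	63
L	W	64
K	M	65
L	Q	66
C	W	67
E	V	68
D	V	69
M	R	70
I	N	71
S	W	72
I	K	73
G	W	74
I	R	75
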