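count	freq	cdr3nt	cdr3aa	v	d	j	VEnd	DStart	DEnd	JStart
1	0.125	TGTGCCTGTGACACCCTAGGAGACACCGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2	TRDD2	TRDJ1	14	16	20	22
1	0.125	TGTGCCTGTGACACCCTGGGGGATACCGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2	TRDD3	TRDJ1	14	15	23	24
1	0.125	TGTGCCTGTGACACACTGGGGGATACCGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2	TRDD3	TRDJ1	13	14	23	24
1	0.125	TGTGCCTGTGACACGCTGGGGGATACCGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2	TRDD3	TRDJ1	13	15	23	24
1	0.125	TGTGCCTGTGACACTCTGGGGGATACCGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2	TRDD3	TRDJ1	13	15	23	24
1	0.125	TGTGCCTGTGACACTCTGGGGGATACTGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2	TRDD3	TRDJ1	13	15	23	24
1	0.125	TGTGCCTGTGACACACTGGGGGACACCGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2	TRDD3	TRDJ1	13	14	21	22
1	0.125	TGTGCCTGTGACACCCTAGGCGATACCGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2	.	TRDJ1	14	-1	-1	24
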