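class	label	location	count
AT	AT	three_prime_utr	154
AT	AT	five_prime_utr	70
AT	AT	coding	73
AT	AT	undetermined	6
AG	AG	three_prime_utr	42
AG	AG	five_prime_utr	53
AG	AG	coding	155
AG	AG	undetermined	6
AC	AC	three_prime_utr	27
AC	AC	five_prime_utr	18
AC	AC	coding	46
AC	AC	undetermined	3
CG	CG	three_prime_utr	0
CG	CG	five_prime_utr	0
CG	CG	coding	2
CG	CG	undetermined	0
AAG	AAG	three_prime_utr	19
AAG	AAG	five_prime_utr	36
AAG	AAG	coding	285
AAG	AAG	undetermined	2
ATC	ATG	three_prime_utr	19
ATC	ATG	five_prime_utr	32
ATC	ATG	coding	178
ATC	ATG	undetermined	1
AGG	AGG	three_prime_utr	7
AGG	AGG	five_prime_utr	49
AGG	AGG	coding	170
AGG	AGG	undetermined	0
AGC	AGC	three_prime_utr	18
AGC	AGC	five_prime_utr	34
AGC	AGC	coding	129
AGC	AGC	undetermined	2
AAT	AAT	three_prime_utr	55
AAT	AAT	five_prime_utr	22
AAT	AAT	coding	49
AAT	AAT	undetermined	2
ACC	ACC	three_prime_utr	6
ACC	ACC	five_prime_utr	7
ACC	ACC	coding	64
ACC	ACC	undetermined	0
CCG	GGC	three_prime_utr	9
CCG	GGC	five_prime_utr	15
CCG	GGC	coding	38
CCG	GGC	undetermined	0
AAC	AAC	three_prime_utr	11
AAC	AAC	five_prime_utr	9
AAC	AAC	coding	32
AAC	AAC	undetermined	0
ACG	ACG	three_prime_utr	0
ACG	ACG	five_prime_utr	1
ACG	ACG	coding	11
ACG	ACG	undetermined	0
ACT	AGT	three_prime_utr	2
ACT	AGT	five_prime_utr	1
ACT	AGT	coding	4
ACT	AGT	undetermined	0
tetra	tetra	three_prime_utr	61
tetra	tetra	five_prime_utr	65
tetra	tetra	coding	60
tetra	tetra	undetermined	8
penta	penta	three_prime_utr	180
penta	penta	five_prime_utr	193
penta	penta	coding	349
penta	penta	undetermined	19
hexa	hexa	three_prime_utr	154
hexa	hexa	five_prime_utr	225
hexa	hexa	coding	703
hexa	hexa	undetermined	12
compound	compound	three_prime_utr	15
compound	compound	five_prime_utr	5
compound	compound	coding	35
compound	compound	undetermined	1
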