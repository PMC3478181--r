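site	amino_acid	codon	count
89	A	GCG	2
89	C	TTT	2
89	D	CTG	1
89	E	GAG	1
89	F	TTT	1
89	G	GGG	5
89	G	GGT	3
89	L	CTG	1
89	N	AAT	1
89	Q	CAG	1
89	R	CGT	3
89	R	CGC	3
89	T	ACA	1
95	H	CAT	1
95	R	CGG	1
100	I	ATT	2
100	M	ATG	4
100	N	AAT	2
100	Q	CAG	1
100	R	CGG	1
100	R	CGT	3
100	S	AGT	1
144	E	GAG	3
144	G	GGG	4
144	G	GGT	4
144	R	CGG	1
144	V	GTT	3
144	W	TGG	1
147	C	TGT	3
147	N	AAT	3
147	P	CCT	3
147	R	CGT	4
147	R	CGC	3
147	S	TCT	1
147	V	GTG	3
197	A	CGC	1
197	C	TGT	7
197	D	GAT	1
197	G	GGG	3
197	K	AAG	1
197	M	ATG	2
197	Q	CAG	1
197	R	AGG	1
197	S	TCG	5
197	S	AGT	1
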