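sample_id	rsid	gene	ref	alt	ref_reads	alt_reads	gq	test_genotype	truth_genotype	sanger_genotype
S01	rs17885098	CYP2C19	T	C	18	0	54	T/T	T/C	T/T
S02	rs3758581	CYP2C19	G	A	7	0	18	G/G	G/A	G/G
S03	rs1135840	CYP2D6	G	C	29	19	99	G/C	C/C	C/C
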