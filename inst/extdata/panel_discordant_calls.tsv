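sample_id	rsid	gene	ref	alt	ref_reads	alt_reads	gq	test_genotype	truth_genotype	sanger_genotype
S01	rs1902023	UGT2B15	A	C	0	5	15	A/C	C/C	A/C
S02	rs72552763	SLC22A1	G	T	6	4	99	G/T	T/T	G/T
S03	rs3740066	ABCC2	C	T	15	16	99	C/T	T/T	C/T
S04	rs3740066	ABCC2	C	T	17	15	99	C/T	T/T	C/T
S05	rs9282861	SULT1A1	G	A	7	0	18	A/A	G/A	A/A
S06	rs9282861	SULT1A1	G	A	8	0	24	A/A	G/A	A/A
S07	rs9282861	SULT1A1	G	A	4	0	12	A/A	G/A	A/A
S08	rs9282861	SULT1A1	G	A	13	0	39	A/A	G/A	A/A
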