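sample_id	rsid	contig	position	ref	alt	genotype	call_rate	gene
S01	rs4244285	chr10	96541616	G	A	G/A	97.2	CYP2C19
S01	rs3758581	chr10	96602623	A	G	A/A	94.8	CYP2C19
S01	rs3892097	chr22	42524947	C	T	C/T	91.5	CYP2D6
S02	rs4244285	chr10	96541616	G	A	G/G	88.1	CYP2C19
S02	rs3758581	chr10	96602623	A	G		0	CYP2C19
S02	rs3892097	chr22	42524947	C	T	C/C	84.9	CYP2D6
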