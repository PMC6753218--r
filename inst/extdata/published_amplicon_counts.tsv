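case	gene	variant	subject	assay	ref_count	var_count	printed_percent
Case 61	KCNQ2	c.643G>A:p.Gly215Arg	proband	panel	1920	170	8.7
Case 61	KCNQ2	c.643G>A:p.Gly215Arg	proband	amplicon	54190	9933	15.45
Case 61	KCNQ2	c.643G>A:p.Gly215Arg	mother	amplicon	59508	137	0.23
Case 61	KCNQ2	c.643G>A:p.Gly215Arg	father	amplicon	55091	128	0.23
Case 42	SCN8A	c.2105G>C:p.Ser702Thr	proband	panel	2427	167	6.4
Case 42	SCN8A	c.2105G>C:p.Ser702Thr	proband	amplicon	19035	4535	19.2
Case 42	SCN8A	c.2105G>C:p.Ser702Thr	mother	amplicon	15401	129	0.83
Case 42	SCN8A	c.2105G>C:p.Ser702Thr	father	amplicon	17973	110	0.61
Case 5	GABRA1	c.1015A>G:p.Lys339Glu	proband	panel	1238	1242	50.1
Case 5	GABRA1	c.1015A>G:p.Lys339Glu	proband	amplicon	59872	53604	47.2
Case 5	GABRA1	c.1015A>G:p.Lys339Glu	mother	amplicon	100118	18074	15.3
Case 5	GABRA1	c.1015A>G:p.Lys339Glu	father	amplicon	118255	1269	1.06
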