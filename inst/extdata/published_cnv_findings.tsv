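case	chrom_position_hg19	size_mb	genes	onset	onset_days	syndrome
Case 92	Chr2:165755330-168986256	3.23	SCN2A;SCN1A;SCN9A	2 months	61	Dravet syndrome
Case 16	Chr16:29652999-30198600	0.54	PRRT2	4 months	122	unclassified
Case 32	Chr16:29673954-30119759	0.44	PRRT2	4 days	4	Benign infantile epilepsy
Case 18	Chr20:61472348-62281707	0.80	CHRNA4;KCNQ2	2 months	61	unclassified
Case 80	Chr20:61845191-62065069	0.21	CHRNA4;KCNQ2	1 day	1	Benign infantile epilepsy
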