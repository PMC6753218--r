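case_id	onset_days	syndrome	gene	variant_class	classification
Case 29	NA	NA	ARHGEF9	sequence	Pathogenic
Case 75	NA	NA	ATP1A2	sequence	Pathogenic
Case 8	NA	NA	ATP1A3	sequence	Likely Pathogenic
Case 5	NA	NA	GABRA1	sequence	Likely Pathogenic
Case 66	NA	NA	GABRB3	sequence	Likely Pathogenic
Case 2	NA	NA	GLRA1	sequence	Likely Pathogenic
Case 82	NA	NA	HCN1	sequence	Likely Pathogenic
Case 73	NA	NA	KCNA2	sequence	Likely Pathogenic
Case 85	NA	NA	KCNQ2	sequence	Pathogenic
Case 14	NA	NA	KCNQ2	sequence	Pathogenic
Case 11	NA	NA	KCNQ2	sequence	Pathogenic
Case 57	NA	NA	KCNQ2	sequence	Pathogenic
Case 68	NA	NA	KCNQ2	sequence	Pathogenic
Case 39	NA	NA	KCNQ3	sequence	Likely Pathogenic
Case 56	NA	NA	PCDH19	sequence	Likely Pathogenic
Case 96	NA	NA	PCDH19	sequence	Likely Pathogenic
Case 51	NA	NA	PRRT2	sequence	Pathogenic
Case 43	NA	NA	PRRT2	sequence	Pathogenic
Case 58	NA	NA	PRRT2	sequence	Pathogenic
Case 71	NA	NA	PRRT2	sequence	Pathogenic
Case 77	NA	NA	PRRT2	sequence	Pathogenic
Case 78	NA	NA	PRRT2	sequence	Pathogenic
Case 81	NA	NA	PRRT2	sequence	Pathogenic
Case 83	NA	NA	PRRT2	sequence	Pathogenic
Case 105	NA	NA	PRRT2	sequence	Pathogenic
Case 34	NA	NA	PRRT2	sequence	Pathogenic
Case 26	NA	NA	SCN1A	sequence	Pathogenic
Case 101	NA	NA	SCN1A	sequence	Pathogenic
Case 48	NA	NA	SCN1A	sequence	Pathogenic
Case 40	NA	NA	SCN1A	sequence	Likely Pathogenic
Case 13	NA	NA	SCN1A	sequence	Pathogenic
Case 54	NA	NA	SCN1A	sequence	Pathogenic
Case 100	NA	NA	SCN1B	sequence	Pathogenic
Case 25	NA	NA	SCN2A	sequence	Likely Pathogenic
Case 45	NA	NA	SCN2A	sequence	Likely Pathogenic
Case 33	NA	NA	SCN2A	sequence	Likely Pathogenic
Case 31	NA	NA	SCN2A	sequence	Likely Pathogenic
Case 104	NA	NA	SCN8A	sequence	Likely Pathogenic
Case 111	NA	NA	SCN8A	sequence	Likely Pathogenic
Case 79	NA	NA	SCN8A	sequence	Likely Pathogenic
Case 47	NA	NA	SLC2A1	sequence	Likely Pathogenic
Case 12	NA	NA	SLC2A1	sequence	Likely Pathogenic
Case 93	NA	NA	SLC2A1	sequence	Likely Pathogenic
Case 17	NA	NA	STXBP1	sequence	Pathogenic
Case 109	NA	NA	STXBP1	sequence	Likely Pathogenic
Case 64	NA	NA	STXBP1	sequence	Pathogenic
Case 1	NA	NA	SYNGAP1	sequence	Pathogenic
Case 36	NA	NA	SYNGAP1	sequence	Pathogenic
Case 92	61	Dravet syndrome	SCN2A;SCN1A;SCN9A	CNV	Pathogenic
Case 16	122	unclassified	PRRT2	CNV	Pathogenic
Case 32	4	Benign infantile epilepsy	PRRT2	CNV	Pathogenic
Case 18	61	unclassified	CHRNA4;KCNQ2	CNV	Pathogenic
Case 80	1	Benign infantile epilepsy	CHRNA4;KCNQ2	CNV	Pathogenic
Undiagnosed 01 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 02 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 03 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 04 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 05 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 06 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 07 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 08 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 09 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 10 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 11 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 12 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 13 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 14 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 15 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 16 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 17 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 18 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 19 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 20 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 21 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 22 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 23 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 24 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 25 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 26 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 27 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 28 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 29 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 30 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 31 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 32 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 33 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 34 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 35 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 36 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 37 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 38 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 39 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 40 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 41 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 42 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 43 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 44 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 45 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 46 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 47 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 48 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 49 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 50 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 51 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 52 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 53 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 54 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 55 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 56 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 57 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 58 (synthetic placeholder)	NA	NA	none	none	none
Undiagnosed 59 (synthetic placeholder)	NA	NA	none	none	none
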