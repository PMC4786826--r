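subject_id	pair_id	sex	age	bmi	selfreport_concordance	mri_concordance	selfreport_note	mri_note
19	1	F	48	29.39	Concordant	Concordant	Some LBP in past year	Normal
20	1	F	48	31.23	Concordant	Concordant	Some LBP in past year	Normal
45	2	M	47	27.12	Concordant	Concordant	No history of LBP	Normal
46	2	M	47	24.82	Concordant	Concordant	No history of LBP	Normal
85	3	M	46	28.71	Concordant	Concordant	No history of LBP	Normal
86	3	M	46	24.97	Concordant	Concordant	No history of LBP	Normal
125	4	F	43	22.13	Concordant	Discordant	No history of LBP	Normal
126	4	F	43	23.3	Concordant	Discordant	No history of LBP	Hemangioma L4
189	5	M	48	22.13	Concordant	Concordant	3 days mild LBP in last year	Normal
190	5	M	48	23.3	Concordant	Concordant	3 days mild LBP in last year	Normal
13	6	M	44	20.58	Discordant	Discordant	No history of LBP	Normal
14	6	M	44	21.45	Discordant	Discordant	Compression fracture 1996	Comp.Fracture L1
299	7	F	48	27.1	Discordant	Discordant	Daily LBP with sciatica.	Disc Degeneration L1
300	7	F	48	25.59	Discordant	Discordant	No history of LBP	Normal
353	8	M	45	23.55	Discordant	Discordant	No history of LBP	Schmorl's Node L2
354	8	M	45	26.3	Discordant	Discordant	Daily LBP/Prior disc surgery	Laminectomy L4-5
391	9	M	43	31.46	Discordant	Discordant	No history of LBP	Hemilaminectomy L4
392	9	M	43	31.86	Discordant	Discordant	Prior disc surgery	Disc Degeneration L3-4
393	10	F	43	26.03	Discordant	Discordant	Frequent LBP	Normal
394	10	F	43	26.13	Discordant	Discordant	No history of LBP	Disc Prolapse L4-5
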