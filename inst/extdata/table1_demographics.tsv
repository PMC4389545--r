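age_group	total	female	ixi	mcbi	nihpd	oasis_cs	oasis_long
20-24	244	139	42	88	26	88	0
25-29	101	62	58	15	0	28	0
30-34	79	29	52	16	0	11	0
35-39	50	22	44	1	0	5	0
40-44	61	37	47	4	0	10	0
45-49	65	33	41	3	0	21	0
50-54	57	38	38	2	0	17	0
55-59	73	45	55	2	0	16	0
60-64	83	58	61	0	0	11	11
65-69	89	54	51	1	0	14	23
70-74	101	70	37	0	0	24	40
75-79	61	41	12	0	0	9	40
80-84	62	43	6	0	0	17	39
85-89	36	22	2	0	0	12	22
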