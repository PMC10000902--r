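spot_no	label_as_printed	gene	identified_by	ph_range	practical_pi	theoretical_pi	practical_mw_kda	theoretical_mw_kda	dige_cv_tech	dige_sum_cv_tech	dige_cv_total	dige_sum_cv_total	shotgun_cv_tech	shotgun_cv_total	spot_size	lfq_intensity	excluded_from_correlation
1	1	CALM1	2D-WB	4-7	3.66	4.09	14.1	16.8	3.9	33	12.9	34.2	15	55	9.7	218110164	TRUE
2	2	CALM1	MS	4-7	4.09	NA	16.8	NA	62.2	33	55.4	34.2	15	55	38.8	218110164	TRUE
3	3	PTGES3	MS	4-7	3.79	4.32	20.8	19.2	3.8	5.1	8.6	9.2	33.7	67.6	18.4	23571667	FALSE
4	4	PTGES3	2D-WB	4-7	3.87	NA	20.8	NA	6.4	5.1	9.8	9.2	33.7	67.6	5.5	23571667	FALSE
5	5	YWHAG	MS	4-7	4.70	4.80	29.1	28.3	4.5	4.5	1.8	1.8	18.8	44.36	25.4	3275800	FALSE
6	6	P4HB	MS	4-7	4.72	4.76	58.3	57.1	3.3	4.5	3.7	5.5	8.9	63.2	12.7	63695001	FALSE
7	7	P4HB	MS	4-7	4.76	NA	57.1	NA	2.5	4.5	5.0	5.5	8.9	63.2	147	63695001	FALSE
8	8	P4HB	MS	4-7	4.78	NA	59.5	NA	8.8	4.5	9.6	5.5	8.9	63.2	5.9	63695001	FALSE
9	9	P4HB	MS	4-7	4.84	NA	58.0	NA	3.6	4.5	3.7	5.5	8.9	63.2	19.4	63695001	FALSE
10	10	CTSB	2D-WB	4-7	5.43	5.88	27.8	37.8	1.5	7.7	11.8	10.1	23.4	39.6	7.9	1219708	FALSE
11	11	CTSB	MS	4-7	5.53	NA	26.1	NA	14.4	7.7	5.1	10.1	23.4	39.6	3.4	1219708	FALSE
12	12	CTSB	MS	4-7	5.54	NA	27.0	NA	7.1	7.7	13.5	10.1	23.4	39.6	5.6	1219708	FALSE
13	13	CTSD	MS	4-7	5.76	6.10	30.4	43.7	3.1	2.5	6.4	21.2	17.4	60.7	5.2	5884650	FALSE
14	14	CTSD	MS	4-7	5.97	NA	28.8	NA	1.9	2.5	36.1	21.2	17.4	60.7	24.1	5884650	FALSE
15	15	PKM2	MS	4-7	5.80	7.96	59.3	57.9	4.6	6.3	4.6	15.1	27.3	66.0	11.3	22507667	FALSE
16	16	PKM2	MS	4-7	6.08	NA	58.3	NA	3.7	6.3	5.3	15.1	27.3	66.0	17.8	22507667	FALSE
17	17	PKM2	2D-WB	6-9	7.50	NA	57.6	NA	6.8	6.3	11.9	15.1	27.3	66.0	104.8	22507667	FALSE
18	18	PKM2	MS	6-9	7.75	NA	57.7	NA	8.2	6.3	19.7	15.1	27.3	66.0	38.7	22507667	FALSE
19	19	PKM2	MS	6-9	7.32	NA	42.0	NA	7.1	6.3	42.2	15.1	27.3	66.0	14.6	22507667	FALSE
20	20	PKM2	MS	6-9	7.96	NA	57.9	NA	7.9	6.3	17.9	15.1	27.3	66.0	391.3	22507667	FALSE
21	21	PKM2	MS	6-9	8.20	NA	57.4	NA	5.6	6.3	4.0	15.1	27.3	66.0	9.3	22507667	FALSE
22	22	EIF4A1	MS	4-7	5.81	5.32	48.6	46.2	3.0	2	13.2	11.8	11.0	48.8	80.6	41301834	FALSE
23	23	EIF4A1	MS	4-7	5.90	NA	47.8	NA	2.7	2	10.5	11.8	11.0	48.8	70	41301834	FALSE
24	24	TALDO1	2D-WB	4-7	6.33	6.36	39.1	37.5	2.3	4.6	16.0	15.9	15.0	51.1	9.7	14659166	FALSE
25	25	TALDO1	MS	4-7	6.82	NA	38.0	NA	4.2	4.6	14.4	15.9	15.0	51.1	19.1	14659166	FALSE
26	26	TALDO1	MS	4-7	7.32	NA	39.2	NA	7.4	4.6	16.9	15.9	15.0	51.1	20.3	14659166	FALSE
27	27	CAP1	MS	6-9	6.83	8.24	54.9	51.9	4.0	5.9	19.3	12.9	21.3	47.9	6.2	18092833	FALSE
28	28	CAP1	2D-WB	6-9	6.95	NA	55.1	NA	7.8	5.9	8.4	12.9	21.3	47.9	10.9	18092833	FALSE
29	29	CAP1	2D-WB	6-9	7.14	NA	55.5	NA	5.5	5.9	17.1	12.9	21.3	47.9	8.0	18092833	FALSE
30	30	CAP1	MS	6-9	7.38	NA	54.8	NA	4.4	5.9	11.2	12.9	21.3	47.9	21.4	18092833	FALSE
31	31	CAP1	2D-WB	6-9	7.66	NA	55.1	NA	7.7	5.9	8.7	12.9	21.3	47.9	3.7	18092833	FALSE
32	32	GAPDH	MS	6-9	8.68	8.57	39.1	36.1	9.1	5.6	32.5	20.6	13.9	53.6	62.8	191046667	FALSE
33	31	GAPDH	MS	6-9	8.78	NA	39.0	NA	7.7	5.6	25.1	20.6	13.9	53.6	626.3	191046667	FALSE
34	34	GAPDH	2D-WB	6-9	8.88	NA	39.1	NA	4.7	5.6	30.8	20.6	13.9	53.6	55.5	191046667	FALSE
35	35	GAPDH	2D-WB	6-9	9.01	NA	39.0	NA	3.1	5.6	5.3	20.6	13.9	53.6	13.0	191046667	FALSE
36	36	GAPDH	MS	6-9	9.21	NA	38.8	NA	3.3	5.6	9.5	20.6	13.9	53.6	5.6	191046667	FALSE
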