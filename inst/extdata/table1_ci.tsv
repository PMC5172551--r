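# Transcription of the published per-patient prednisolone-inhibitor synergy
# table: single-agent IC50s in nM with maximal effect (% of responding cells)
# in parentheses, mean combination index +/- SD at effect levels ED50 and
# ED75, and the printed synergy label. "<0.10" entries are upper bounds; an
# entry without an SD was computed on fewer than three ratios; NA = not
# applicable (effect level not reached), ND = not determined (efficacy < 20%
# or untested). Two printed max-effect values are corrected OCR artifacts:
# patient 2322 trametinib inhibitor "(465)" -> "(46%)" and patient 3594
# everolimus prednisolone "(66)" -> "(66%)".
patient	inhibitor	target	pred_ic50	inh_ic50	ed50	ed75	label
9858	Ruxolitinib	JAK1	18 (80%)	205 (<20%)	1.40	NA	No synergy
9858	AZD6244	MEK1/2	17 (77%)	71 (76%)	0.61 +/- 0.04	0.13 +/- 0.04	Synergy/strong synergy
9858	Trametinib	MEK1/2	14 (73%)	11 (79%)	0.86 +/- 0.27	0.26 +/- 0.18	Strong synergy
9858	MK2206	AKT	18 (74%)	60 (27%)	0.98 +/- 0.36	NA	No synergy
9858	AZD8055	mTOR	12 (74%)	288 (74%)	0.67 +/- 0.14	NA	Synergy
9858	Everolimus	mTOR	17 (75%)	12614 (<20%)	0.61	<0.10	Synergy/strong synergy
9858	NVPBEZ235	mTOR/PI3K	14 (72%)	322 (59%)	0.98 +/- 0.19	NA	No synergy
1570	Ruxolitinib	JAK1	25 (65%)	58 (<20%)	1.49 +/- 0.74	NA	No synergy
1570	AZD6244	MEK1/2	36 (73%)	647 (40%)	0.57 +/- 0.50	NA	No synergy
1570	Trametinib	MEK1/2	19 (53%)	49 (24%)	0.46 +/- 0.16	NA	Synergy
1570	MK2206	AKT	20 (63%)	464 (39%)	1.12 +/- 0.62	NA	No synergy
1570	AZD8055	mTOR	29 (82%)	22 (<20%)	0.55	NA	Synergy
1570	Everolimus	mTOR	21 (62%)	72 (<20%)	0.85	NA	Synergy
1570	NVPBEZ235	mTOR/PI3K	57 (79%)	728 (69%)	0.54 +/- 0.06	0.39 +/- 0.42	Synergy
2911	Ruxolitinib	JAK1	9007 (<20%)	5323 (59%)	1.65 +/- 0.28	NA	No synergy
2911	AZD6244	MEK1/2	425 (<20%)	246 (58%)	0.61 +/- 0.59	NA	No synergy
2911	Trametinib	MEK1/2	90 (<20%)	81 (75%)	0.90 +/- 0.25	NA	No synergy
2911	MK2206	AKT	154 (<20%)	239 (51%)	0.22 +/- 0.07	NA	Strong synergy
2911	AZD8055	mTOR	104 (<20%)	251 (64%)	0.44 +/- 0.09	NA	Synergy
2911	Everolimus	mTOR	560 (<20%)	68 (51%)	NA	NA	NA
2911	NVPBEZ235	mTOR/PI3K	>10000 (<20%)	362 (71%)	0.30 +/- 0.05	NA	Synergy
491	Ruxolitinib	JAK1	120 (87%)	ND (<20%)	NA	NA	NA
491	AZD6244	MEK1/2	80 (70%)	141 (41%)	0.29 +/- 0.13	<0.10	Strong synergy
491	Trametinib	MEK1/2	105 (67%)	13 (24%)	0.33 +/- 0.17	NA	Synergy
491	MK2206	AKT	123 (61%)	ND (<20%)	0.70	NA	Synergy
491	AZD8055	mTOR	78 (82%)	ND (<20%)	1.41	NA	No synergy
491	Everolimus	mTOR	61 (76%)	ND (<20%)	0.79	0.41	Synergy
491	NVPBEZ235	mTOR/PI3K	95 (62%)	ND (<20%)	0.60	NA	Synergy
1032	Ruxolitinib	JAK1	38 (91%)	ND (<20%)	1.12	1.08	No synergy
1032	AZD6244	MEK1/2	41 (89%)	259 (18%)	0.70 +/- 0.08	0.88 +/- 0.05	Synergy
1032	Trametinib	MEK1/2	40 (89%)	50 (25%)	0.65 +/- 0.05	0.79 +/- 0.16	Synergy
1032	MK2206	AKT	37 (87%)	520 (81%)	0.96 +/- 0.09	0.70 +/- 0.11	Synergy
1032	AZD8055	mTOR	39 (91%)	61 (68%)	0.98 +/- 0.13	0.58 +/- 0.21	Synergy
1032	Everolimus	mTOR	36 (89%)	11 (51%)	0.46 +/- 0.01	0.84 +/- 0.08	Synergy
1032	NVPBEZ235	mTOR/PI3K	38 (89%)	134 (64%)	1.24 +/- 0.04	0.63 +/- 0.32	Synergy
1815	Ruxolitinib	JAK1	108 (52%)	ND (<20%)	1.39	NA	No synergy
1815	AZD6244	MEK1/2	116 (59%)	151 (53%)	0.13 +/- 0.03	<0.10	Strong synergy
1815	Trametinib	MEK1/2	141 (50%)	23 (53%)	0.16 +/- 0.07	<0.10	Strong synergy
1815	MK2206	AKT	119 (52%)	165 (50%)	0.19 +/- 0.07	<0.10	Strong synergy
1815	AZD8055	mTOR	173 (68%)	52 (58%)	0.41 +/- 0.06	<0.10	Synergy/strong synergy
1815	Everolimus	mTOR	120 (59%)	11 (36%)	0.25 +/- 0.06	NA	Strong synergy
1815	NVPBEZ235	mTOR/PI3K	138 (53%)	196 (57%)	0.79 +/- 0.05	<0.10	Synergy/strong synergy
2322	Ruxolitinib	JAK1	122 (27%)	ND (<20%)	NA	NA	NA
2322	AZD6244	MEK1/2	49 (28%)	223 (48%)	NA	NA	NA
2322	Trametinib	MEK1/2	ND (<20%)	87 (46%)	<0.10	NA	Strong synergy
2322	MK2206	AKT	86 (13%)	504 (58%)	0.10 +/- 0.02	<0.10	Strong synergy
2322	AZD8055	mTOR	107 (30%)	90 (57%)	0.46 +/- 0.15	<0.10	Synergy/strong synergy
2322	Everolimus	mTOR	ND	ND	ND	ND	ND
2322	NVPBEZ235	mTOR/PI3K	73 (21%)	337 (92%)	0.52 +/- 0.14	0.59 +/- 0.29	Synergy
10110	Ruxolitinib	JAK1	28 (84%)	122 (79%)	1.12 +/- 0.11	0.82 +/- 0.25	No synergy
10110	AZD6244	MEK1/2	ND	ND	ND	ND	ND
10110	Trametinib	MEK1/2	ND	ND	ND	ND	ND
10110	MK2206	AKT	39 (67%)	4035 (72%)	0.95 +/- 0.13	<0.10	Strong synergy
10110	AZD8055	mTOR	40 (86%)	84 (72%)	0.96 +/- 0.01	0.65 +/- 0.25	Synergy
10110	Everolimus	mTOR	43 (92%)	14 (54%)	0.70 +/- 0.17	0.53 +/- 0.16	Synergy
10110	NVPBEZ235	mTOR/PI3K	35 (74%)	186 (50%)	1.21 +/- 0.17	<0.10	Strong synergy
3594	Ruxolitinib	JAK1	46 (55%)	ND (<20%)	1.55	NA	No synergy
3594	AZD6244	MEK1/2	63 (65%)	79 (72%)	0.38 +/- 0.03	<0.10	Synergy/strong synergy
3594	Trametinib	MEK1/2	60 (62%)	16 (76%)	0.46 +/- 0.12	<0.10	Synergy/strong synergy
3594	MK2206	AKT	45 (52%)	2029 (100%)	0.78 +/- 0.09	0.32 +/- 0.20	Synergy
3594	AZD8055	mTOR	48 (63%)	142 (60%)	0.78 +/- 0.31	<0.10	Strong synergy
3594	Everolimus	mTOR	62 (66%)	ND (<20%)	0.41	<0.10	Strong synergy
3594	NVPBEZ235	mTOR/PI3K	36 (49%)	326 (69%)	0.64 +/- 0.43	<0.10	Strong synergy
4992	Ruxolitinib	JAK1	60 (94%)	2384 (38%)	0.85 +/- 0.18	1.00 +/- 0.11	No synergy
4992	AZD6244	MEK1/2	50 (90%)	99 (45%)	0.43 +/- 0.20	0.44 +/- 0.14	Synergy
4992	Trametinib	MEK1/2	63 (93%)	61 (42%)	0.49 +/- 0.15	0.54 +/- 0.13	Synergy
4992	MK2206	AKT	112 (87%)	723 (54%)	0.55 +/- 0.13	0.49 +/- 0.15	Synergy
4992	AZD8055	mTOR	44 (96%)	14 (57%)	1.02 +/- 0.13	0.60 +/- 0.17	Synergy
4992	Everolimus	mTOR	38 (91%)	2 (50%)	0.34 +/- 0.07	0.67 +/- 0.05	Synergy
4992	NVPBEZ235	mTOR/PI3K	103 (84%)	496 (52%)	0.61 +/- 0.22	0.44 +/- 0.19	Synergy
9791	Ruxolitinib	JAK1	79 (45%)	ND (<20%)	NA	NA	NA
9791	AZD6244	MEK1/2	59 (38%)	188 (48%)	NA	NA	Synergy
9791	Trametinib	MEK1/2	50 (40%)	217 (76%)	0.11 +/- 0.08	NA	Strong synergy
9791	MK2206	AKT	56 (41%)	59 (59%)	0.81 +/- 0.36	NA	No synergy
9791	AZD8055	mTOR	60 (43%)	91 (90%)	0.54 +/- 0.18	0.41 +/- 0.11	Synergy
9791	Everolimus	mTOR	40 (44%)	1 (50%)	NA	NA	NA
9791	NVPBEZ235	mTOR/PI3K	41 (46%)	148 (89%)	0.60 +/- 0.31	0.61 +/- 0.13	Synergy
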