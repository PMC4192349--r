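region_id	replicon	start	end	printed_length	end_unreliable	gene_left	fc_left	footnote_left	gene_right	fc_right	footnote_right	binding_site
R01	chromosome	136127	136558	431	FALSE	all0131	Low coverage	none	alr0132	-1.1	none	Yes
R02	chromosome	613436	613919	483	FALSE	patA (all0521)	-8.0	none	alr0522	-5.6	d	Yes
R03	chromosome	1729122	1729569	447	FALSE	all1467	1.4	none	alr1468	Low coverage	none	Yes
R04	chromosome	1732738	1733693	955	FALSE	asr1469	1.7	c	alr1470	-3.1	none	Yes
R05	chromosome	1734763	1735224	461	FALSE	all1471	-2.3	none	all1472	-1.6	c	Yes
R06	chromosome	1788499	1788932	433	FALSE	alr1527	-5.8	none	alr1528	NA	b	Yes
R07	chromosome	2427714	2428147	433	FALSE	all2027	3.8	none	asl2028	-1.5	none	Yes
R08	chromosome	2691579	2692024	445	FALSE	all2239	-4.0	none	alr2240	-7.1	none	Yes
R09	chromosome	2820376	2822006	678	TRUE	alr2338	-4.4	c	hetR (alr2339)	-131	none	Yes
R10	chromosome	3431297	3432038	741	FALSE	hetC (alr2817)	NA	c	hetP (alr2818)	-4.4	none	Yes
R11	chromosome	3627499	3627977	478	FALSE	alr2986	-3.0	c	alr2987	NA	d	Yes
R12	chromosome	3695599	3696450	851	FALSE	asr3053	2.1	c	all3054	NA	d	Yes
R13	chromosome	3821175	3821606	431	FALSE	alr3156	NA	c	aphA (alr3157)	-7.7	none	Yes
R14	chromosome	4383426	4383866	440	FALSE	avaIR (all3631)	-1.3	d	avaIM (all3632)	-1.9	c	Yes
R15	chromosome	4539927	4540364	437	FALSE	alr3757	NA	c	alr3758	11 / 0	none	Yes
R16	chromosome	4740704	4741151	447	FALSE	alr3926	NA	c	all3927	-2.9	c	Yes
R17	chromosome	5064797	5065242	445	FALSE	asr4228	NA	c	alr4229	-7.5	none	Yes
R18	chromosome	5303024	5303480	456	FALSE	all4424	5.2	none	all4425	1.7	c	Yes
R19	chromosome	5309952	5310383	431	FALSE	all4430	4.9	none	all4431	10.3	c	Yes
R20	chromosome	5355615	5356047	432	FALSE	alr4469	-1.3	c	asr4470	-10.8	none	Yes
R21	chromosome	374646	375090	444	FALSE	all0326	Low coverage	none	all0327	NA	c	No
R22	chromosome	2274728	2275590	862	FALSE	alr1903	-4.9	c	cyaB2 (all1904)	NA	c	No
R23	chromosome	2693489	2693944	455	FALSE	alr2241	NA	c	alr2242	-13.4	none	No
R24	chromosome	2706756	2707187	431	FALSE	gvpA (asl2254)	-6.3	none	asr2255	Low coverage	none	No
R25	chromosome	4857231	4857672	441	FALSE	alr4031	NA	c	alr4032	Low coverage	none	No
R26	chromosome	6129044	6129475	431	FALSE	all5131	-4.2	none	all5132	-2.5	c	No
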