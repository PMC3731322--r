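sep_mm	a	b	c	se_a	se_b	se_c	adj_r2	n	sens0_pct	sens5_pct	sens10_pct
5	0.0000	0.0058	0.8042	0.0001	0.0003	0.0185	0.526	378	0.58	0.19	0.06
10	-0.0001	0.0133	0.8176	0.0001	0.0005	0.0132	0.647	399	1.32	0.48	0.17
15	-0.0002	0.0261	0.8292	0.0003	0.0009	0.0113	0.687	399	2.59	1.00	0.38
20	-0.0003	0.0431	0.8377	0.0004	0.0013	0.0091	0.753	399	4.27	1.74	0.70
25	-0.0005	0.0614	0.8448	0.0005	0.0017	0.0078	0.793	399	6.09	2.59	1.09
30	-0.0006	0.0781	0.8483	0.0006	0.0019	0.0067	0.832	399	7.74	3.37	1.44
35	-0.0008	0.0913	0.8514	0.0006	0.0020	0.0060	0.857	399	9.05	4.01	1.75
40	-0.0009	0.1018	0.8528	0.0006	0.0021	0.0055	0.875	399	10.09	4.51	1.99
45	-0.0009	0.1095	0.8542	0.0007	0.0021	0.0053	0.883	399	10.86	4.89	2.17
50	-0.0010	0.1157	0.8554	0.0007	0.0022	0.0051	0.889	399	11.47	5.20	2.33
55	-0.0010	0.1231	0.8528	0.0007	0.0022	0.0050	0.901	378	12.21	5.45	2.40
60	-0.0011	0.1264	0.8545	0.0007	0.0023	0.0048	0.905	378	12.53	5.65	2.52
65	-0.0011	0.1321	0.8518	0.0007	0.0023	0.0048	0.914	357	13.09	5.81	2.54
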