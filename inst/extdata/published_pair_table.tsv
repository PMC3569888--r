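diff	n_pairs	pct_total	pct_et1_0_et2_0	pct_et1_0_et2_pos	pct_et1_pos_et2_0	pct_et1_pos_et2_pos
0	5673	29.53	82.95	0.00	0.00	17.05
1	5633	29.32	0.00	40.48	44.70	14.82
2	3170	16.50	0.00	30.57	41.10	28.33
3	1798	9.36	0.00	28.59	31.15	40.27
4	1016	5.29	0.00	26.77	29.82	43.41
5	618	3.22	0.00	29.13	27.51	43.37
6	401	2.09	0.00	30.42	25.69	43.89
7	323	1.68	0.00	25.39	32.51	42.11
8	247	1.29	0.00	16.19	30.36	53.44
9	101	0.53	0.00	26.73	24.75	48.51
10	69	0.36	0.00	20.29	39.13	40.58
>10	165	0.86	0.00	15.15	27.27	57.58
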