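measure_type	channel	stimulus_type	component	mean_I	sd_I	n_I	mean_II	sd_II	n_II	test	t_printed	df_printed	p_printed	d_printed	t_consistent	d_consistent
amplitude	Fz	standard	N1	-2.27	1.99	19	-2.23	2.27	20	student	-0.056	37	0.955	0.019	1	1
amplitude	Fz	deviant	N1	-5.05	2.51	19	-5.05	2.55	20	student	0.148	37	0.883	0.000	0	1
amplitude	Fz	standard	P2	3.26	1.33	19	5.18	2.71	20	welch	-2.843	27.944	0.008	0.899	1	1
amplitude	Fz	deviant	P2	4.33	2.22	19	6.99	2.72	20	welch	-2.795	23.607	0.010	1.071	0	1
amplitude	Cz	standard	N1	-2.41	1.97	19	-2.51	2.18	20	student	1.439	37	0.159	0.048	0	1
amplitude	Cz	deviant	N1	-4.54	2.64	19	-4.69	2.65	20	student	0.177	37	0.861	0.057	1	1
amplitude	Cz	standard	P2	3.82	1.13	19	6.00	3.29	20	student	2.981	37	0.005	0.886	0	1
amplitude	Cz	deviant	P2	5.30	2.11	19	8.15	3.20	20	welch	-3.290	33.053	0.002	1.052	1	1
latency	Fz	standard	N1	92.68	7.48	19	89.55	6.09	20	student	1.439	37	0.159	0.176	1	0
latency	Fz	deviant	N1	94.05	8.05	19	92.90	8.69	20	student	1.182	37	0.245	0.137	0	1
latency	Fz	standard	P2	186.79	31.87	19	189.50	20.91	20	welch	-0.312	30.848	0.757	0.101	1	1
latency	Fz	deviant	P2	213.58	27.72	19	190.85	19.37	20	student	2.981	37	0.005	0.951	1	1
latency	Cz	standard	N1	91.74	7.53	19	89.10	6.38	20	student	0.429	37	0.670	0.378	0	1
latency	Cz	deviant	N1	92.68	7.02	19	92.05	8.17	20	student	0.260	37	0.797	0.083	1	1
latency	Cz	standard	P2	186.79	27.04	19	187.60	21.89	20	student	-0.103	37	0.918	0.033	1	1
latency	Cz	deviant	P2	207.74	29.89	19	191.95	17.14	20	welch	2.010	28.378	0.054	0.648	1	1
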