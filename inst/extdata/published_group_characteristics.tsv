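measure	mean_I	sd_I	n_I	mean_II	sd_II	n_II	test	t_printed	df_printed	p_printed	d_printed
age_yrs	25.1	4.1	19	22.8	3.5	20	NA	NA	NA	0.073	NA
coffee_ml_day	121.1	139.8	19	70.0	137.1	20	NA	NA	NA	0.257	NA
tea_ml_day	44.7	94.1	19	40.0	127.3	20	NA	NA	NA	0.896	NA
kss_before	5.8	1.8	19	6.2	1.5	20	NA	NA	NA	0.446	NA
kss_after	4.5	2.2	19	5.1	2.2	20	NA	NA	NA	0.384	NA
mean_vigilance_score	5.0	0.6	19	4.4	0.8	20	student	2.613	37	0.017	0.86
switch_pct_main_stages	17.4	9.5	19	10.9	5.9	20	welch	2.541	30	0.017	0.85
mean_hr_bpm	62.4	6.9	19	63.6	6.9	20	NA	NA	NA	0.623	NA
mean_scl_us	3.5	4.4	19	2.7	2.8	20	NA	NA	NA	0.518	NA
falling_asleep_count	2.2	2.0	19	3.7	1.7	20	student	-2.487	37	0.018	0.82
c_vhr	0.3	0.2	19	0.5	0.1	20	NA	NA	NA	0.00014	NA
c_vscl	0.1	0.2	19	0.4	0.1	20	NA	NA	NA	0.000014	NA
period_v_s	171.7	25.3	19	204.8	36.9	20	student	-3.255	37	0.002	1.07
period_hr_s	111.3	10.7	19	103.7	17.5	20	NA	NA	NA	0.111	NA
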