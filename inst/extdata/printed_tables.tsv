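table	section	parameter	speed	group	pre	post	delta_pct	p	d	dif_p
1	eccentric_strength	mean_torque	30	intervention	30.79	34.38	11.66	.053	.465	.121
1	eccentric_strength	mean_torque	30	control	25.95	26.27	1.27	.777	.101	.121
1	eccentric_strength	mean_torque	60	intervention	34.91	38.02	8.91	.022	.593	.330
1	eccentric_strength	mean_torque	60	control	28.12	30.27	7.65	.293	.334	.330
1	eccentric_strength	peak_torque	30	intervention	39.56	45.63	15.34	.011	.692	.035
1	eccentric_strength	peak_torque	30	control	35.63	35.93	0.84	.777	.088	.035
1	eccentric_strength	peak_torque	60	intervention	44.06	49.31	11.92	.002	.950	.253
1	eccentric_strength	peak_torque	60	control	37.03	40.57	9.56	.062	.632	.253
1	concentric_strength	mean_torque	30	intervention	23.24	24.47	5.29	.152	.286	.394
1	concentric_strength	mean_torque	30	control	20.10	20.81	3.53	.341	.302	.394
1	concentric_strength	mean_torque	60	intervention	26.48	27.97	5.63	.064	.435	.299
1	concentric_strength	mean_torque	60	control	22.52	23.25	3.24	.367	.285	.299
1	concentric_strength	peak_torque	30	intervention	30.98	33.31	7.52	.077	.404	.145
1	concentric_strength	peak_torque	30	control	27.38	27.55	0.62	.835	.064	.145
1	concentric_strength	peak_torque	60	intervention	34.09	36.48	7.01	.032	.539	.110
1	concentric_strength	peak_torque	60	control	29.33	29.44	0.38	.931	.027	.110
1	flexibility_internal	active_rom	NA	intervention	69.88	70.35	0.67	.410	.062	.464
1	flexibility_internal	active_rom	NA	control	72.46	72.68	0.30	.451	.038	.464
1	flexibility_internal	passive_rom_sub	NA	intervention	55.91	52.59	-5.94	.060	.444	.239
1	flexibility_internal	passive_rom_sub	NA	control	59.46	58.27	-2.00	.590	.168	.239
1	flexibility_internal	passive_rom	NA	intervention	79.55	77.54	-2.53	.179	.255	.116
1	flexibility_internal	passive_rom	NA	control	82.00	83.25	1.52	.356	.292	.116
2	infraspinatus	fascicle_length	NA	intervention	69.47	75.23	8.29	.038	.632	.031
2	infraspinatus	fascicle_length	NA	control	81.04	77.35	-4.55	.287	.549	.031
2	infraspinatus	fascicle_volume	NA	intervention	273.78	291.49	6.47	.248	.224	.265
2	infraspinatus	fascicle_volume	NA	control	305.05	297.60	-2.44	.749	.154	.265
2	infraspinatus	fractional_anisotropy	NA	intervention	.251	.273	8.85	.002	1.251	.004
2	infraspinatus	fractional_anisotropy	NA	control	.279	.267	-4.33	.307	.523	.004
2	supraspinatus	fascicle_length	NA	intervention	37.47	42.38	13.10	.017	.663	.041
2	supraspinatus	fascicle_length	NA	control	39.99	39.59	-1.00	.819	.079	.041
2	supraspinatus	fascicle_volume	NA	intervention	153.18	165.65	8.14	.158	.303	.395
2	supraspinatus	fascicle_volume	NA	control	146.65	164.07	11.88	.246	.418	.395
2	supraspinatus	fractional_anisotropy	NA	intervention	.285	.303	6.32	.028	.584	.031
2	supraspinatus	fractional_anisotropy	NA	control	.295	.289	-1.90	.386	.306	.031
3	eccentric_strength	mean_torque	30	intervention	37.46	38.91	3.88	.278	.302	.259
3	eccentric_strength	mean_torque	30	control	31.60	31.20	1.27	.735	.105	.259
3	eccentric_strength	mean_torque	60	intervention	46.41	48.62	4.76	.401	.232	.422
3	eccentric_strength	mean_torque	60	control	37.79	39.41	4.29	.523	.200	.422
3	eccentric_strength	peak_torque	30	intervention	54.50	61.52	12.88	.113	.454	.113
3	eccentric_strength	peak_torque	30	control	45.76	46.36	1.31	.693	.122	.113
3	eccentric_strength	peak_torque	60	intervention	61.51	67.76	10.16	.153	.405	.200
3	eccentric_strength	peak_torque	60	control	52.81	54.49	3.18	.498	.212	.200
3	concentric_strength	mean_torque	30	intervention	31.79	32.52	2.30	.720	.098	.331
3	concentric_strength	mean_torque	30	control	27.27	26.69	2.13	.793	.081	.331
3	concentric_strength	mean_torque	60	intervention	35.04	37.12	5.94	.100	.474	.440
3	concentric_strength	mean_torque	60	control	29.92	31.51	5.31	.328	.310	.440
3	concentric_strength	peak_torque	30	intervention	46.28	48.37	4.52	.473	.198	.222
3	concentric_strength	peak_torque	30	control	39.37	38.35	-2.60	.713	.114	.222
3	concentric_strength	peak_torque	60	intervention	47.52	52.37	10.21	.019	.718	.146
3	concentric_strength	peak_torque	60	control	40.44	42.23	4.43	.284	.341	.146
3	flexibility_external	active_rom	NA	intervention	104.83	107.88	2.91	.065	.433	.387
3	flexibility_external	active_rom	NA	control	103.92	108.04	3.97	.251	.367	.387
3	flexibility_external	passive_rom_sub	NA	intervention	78.55	81.62	3.91	.023	.591	.294
3	flexibility_external	passive_rom_sub	NA	control	80.12	84.64	5.64	.088	.570	.294
3	flexibility_external	passive_rom	NA	intervention	105.54	108.64	2.94	.024	.583	.379
3	flexibility_external	passive_rom	NA	control	108.32	112.23	3.61	.125	.504	.379
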