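subject	session	pet_co2_mean	pet_co2_sd	pet_o2_mean	pet_o2_sd	d_pco2_mean	d_pco2_sd	d_po2_mean	d_po2_sd	ber_mean	ber_sd
s1	mri	42.6	2.1	99.4	5.0	42.3	2.3	52.6	6.2	1.2	0.1
s2	mri	38.3	1.3	111.5	1.0	36.5	2.0	35.6	1.4	1.0	0.1
s3	mri	35.7	3.8	109.0	3.6	35.4	4.4	41.7	4.3	1.2	0.2
s4	mri	35.4	1.2	114.5	2.1	33.0	1.2	37.1	2.6	1.1	0.1
s5	mri	45.7	2.1	113.9	3.4	42.1	3.2	29.4	3.8	0.7	0.1
s6	mri	33.8	4.0	118.8	4.8	30.5	4.0	25.1	5.3	0.8	0.1
s7	mri	38.9	1.8	116.2	4.6	33.5	1.7	30.8	5.3	0.9	0.1
s8	mri	29.0	1.8	103.9	4.3	27.7	1.9	50.9	5.2	1.8	0.1
s9	mri	38.3	1.3	98.0	2.5	38.1	1.5	55.3	3.0	1.5	0.1
s10	tcd	39.1	1.5	107.3	3.2	39.4	1.5	44.3	3.7	1.1	0.1
s10	mri	41.4	1.8	103.8	3.2	40.1	1.8	43.0	3.8	1.1	0.1
s11	tcd	39.1	2.7	113.9	4.1	38.5	2.8	44.1	4.6	1.1	0.1
s11	mri	33.0	2.9	111.1	5.3	32.3	3.0	37.1	6.1	1.1	0.1
s12	tcd	30.6	3.0	119.4	6.2	29.5	3.0	30.8	7.0	1.0	0.1
s12	mri	38.9	2.5	107.8	4.0	37.8	2.6	39.6	4.6	1.0	0.1
s13	tcd	37.2	0.8	107.3	2.0	37.3	0.9	43.1	2.5	1.2	0.1
s13	mri	40.1	0.9	108.1	3.5	38.5	1.0	41.9	4.3	1.1	0.1
s14	tcd	39.4	1.5	100.9	3.2	38.3	1.8	49.7	4.0	1.3	0.1
s14	mri	36.6	0.7	108.7	1.4	36.0	0.8	40.0	1.8	1.1	0.0
s15	tcd	34.7	2.8	106.4	4.1	34.9	2.9	45.8	4.6	1.3	0.1
s15	mri	36.9	1.9	114.4	2.5	35.6	1.9	34.9	2.7	1.0	0.0
s16	tcd	25.9	3.2	123.8	4.5	26.0	3.3	29.3	5.2	1.1	0.1
s16	mri	34.6	1.3	117.8	2.6	32.4	1.4	34.5	3.1	1.1	0.1
s17	tcd	35.9	0.5	109.1	1.2	35.3	0.5	41.5	1.4	1.2	0.0
s17	mri	35.0	0.6	112.2	1.6	34.1	0.7	38.8	1.9	1.1	0.0
s18	tcd	34.0	1.4	117.1	3.9	33.4	1.4	33.4	4.6	1.0	0.1
s18	mri	35.4	3.2	115.3	10.8	33.8	3.3	38.5	12.9	1.1	0.3
s19	tcd	33.9	0.8	118.2	2.2	29.3	1.0	34.6	2.9	1.2	0.1
s19	mri	36.7	1.0	113.5	2.2	32.2	1.1	39.2	2.4	1.2	0.1
s20	tcd	32.4	2.1	116.6	3.1	29.1	2.6	35.5	4.0	1.2	0.1
s20	mri	34.2	1.9	114.4	4.0	30.2	2.1	38.6	4.8	1.3	0.1
s21	tcd	36.1	4.5	126.4	4.9	28.9	6.8	21.6	6.5	0.7	0.1
s22	tcd	32.4	1.7	117.5	2.8	28.1	2.1	34.1	3.5	1.2	0.1
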