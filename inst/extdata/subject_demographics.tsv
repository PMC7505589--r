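subject	sex	age	tcd	mri_rest	mri_co2
s1	M	35	0	1	1
s2	M	48	0	1	1
s3	M	22	0	1	1
s4	M	46	0	1	0
s5	M	32	0	1	0
s6	M	29	0	1	0
s7	F	45	0	1	0
s8	M	19	0	1	0
s9	M	20	0	1	0
s10	M	38	1	1	1
s11	M	28	1	1	0
s12	M	27	1	1	1
s13	M	32	1	1	1
s14	M	22	1	1	1
s15	M	32	1	1	1
s16	F	26	1	1	1
s17	F	27	1	1	1
s18	F	47	1	1	0
s19	F	25	1	1	0
s20	F	23	1	1	0
s21	F	25	1	0	0
s22	F	23	1	0	0
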