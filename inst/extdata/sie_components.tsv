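complex	dE_vdW	dE_vdW_sd	dE_c	dE_c_sd	gamma_dMSA	gamma_dMSA_sd	dG_R	dG_R_sd	C	C_sd	dG_bind	dG_bind_sd
PMI	-61.11	2.08	-64.99	7.48	-11.67	0.58	63.13	6.73	-2.89	0	-10.71	0.47
pDI	-58.54	2.41	-66.67	9.82	-10.84	0.61	68.98	7.53	-2.89	0	-9.92	1.97
WK23	-36.57	1.11	-15.84	2.87	-6.29	0.12	20.52	3.05	-2.89	0	-6.89	0.3
WW8	-37.82	1.44	-21.58	3.68	-6.91	0.42	26.23	3.45	-2.89	0	-7.09	3.54
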