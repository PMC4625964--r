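complex	dE_ele	dE_ele_sd	dE_vdw	dE_vdw_sd	dG_nonpol	dG_nonpol_sd	dG_pol	dG_pol_sd	minus_TdS	minus_TdS_sd	dG_bind	dG_exp
PMI	-136.2	7.6	-64.8	2.1	-9.5	0.1	158.3	8.7	38.9	1.2	-13.3	-10.1
pDI	-141.9	8.4	-55.1	2.1	-8.5	0.3	161.9	10.2	32.9	1.6	-10.7	-8.5
WK23	-32.9	6.4	-36	1.9	-5.1	0.1	46.7	6.8	18.9	1.1	-8.4	-6.1
WW8	-53.1	6.8	-37.1	1.4	-5.5	0.2	67.1	7.2	19.7	1.5	-8.9	-6.8
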