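complex	donor	acceptor	distance	angle	occupancy
PMI	Trp7'-NE1-HE1	Met53-O	2.83	149.25	92.31
pDI	Trp7'-NE1-HE1	Met53-O	2.91	138.53	90.02
WK23	WK23-N11-H4	Met53-O	2.83	157.25	97.04
WW8	WW8-N8-H3	Met53-O	2.92	146.35	79.24
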