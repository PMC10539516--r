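lg	length_male_cM	length_female_cM	fm_ratio_printed
LG1	106.76	212.20	1.99
LG2	100.83	185.51	1.84
LG3	110.07	182.89	1.66
LG4	111.36	168.42	1.51
LG5	105.22	133.31	1.27
LG6	108.13	163.81	1.52
LG7	102.72	114.08	1.11
LG8	106.62	120.52	1.13
LG9	115.96	111.34	0.96
LG10	108.69	108.21	1.00
LG11	94.21	81.11	0.86
LG12	103.68	103.70	1.00
LG13	106.47	96.04	0.90
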