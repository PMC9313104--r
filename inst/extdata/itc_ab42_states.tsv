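state	Ka	Kd_uM	dH	TdS	dG
E1/E2	7.7e5	1.3	-2.54	5.48	-8.02
E1	3.7e5	2.7	-1.54	6.02	-7.56
E2	4.9e5	2.0	-2.21	5.55	-7.76
E2P	5.1e5	2.0	-1.59	6.19	-7.78
OBN	8.3e5	1.2	-1.21	6.87	-8.08
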