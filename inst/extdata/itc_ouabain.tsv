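state	Kd_uM	dH	TdS
Ab42_complex	0.12	-20.2	-10.8
E2P_free	0.10	-13.7	-4.2
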