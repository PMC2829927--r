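id	raf	grr	a	ve
rs2188962	0.425	1.25	0.083	.0034
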