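roi	x	y	z	radius_mm
pMTG	-54	-46	8	12
aIPS	-42	-40	47	12
PMv	-48	5	44	12
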