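roi	x	y	z	radius_mm
pMTG	-51	-55	5	12
SMG	-57	-38	34	12
PMv	-42	2	44	12
aIPS	-39	-37	44	12
PMd	-27	-7	62	12
SPOC	-24	-76	29	12
SPL	-30	-52	56	12
M1	-36	-28	59	12
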