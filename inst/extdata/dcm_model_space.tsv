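model_id	pMTG_to_aIPS	pMTG_to_PMv	aIPS_to_pMTG	PMv_to_pMTG	aIPS_to_PMv	PMv_to_aIPS
1	1	1	1	1	1	1
2	1	1	1	1	1	0
3	1	1	1	1	0	1
4	1	1	0	0	1	1
5	0	0	1	1	1	1
6	1	1	1	1	0	0
7	1	1	0	0	1	0
8	1	1	0	0	0	1
9	0	0	1	1	1	0
10	0	0	1	1	0	1
11	0	0	0	0	1	1
12	1	1	0	0	0	0
13	0	0	1	1	0	0
14	0	0	0	0	1	0
15	0	0	0	0	0	1
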