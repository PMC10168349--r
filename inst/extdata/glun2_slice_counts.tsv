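mouse	slice	n_tdt	n_2d	n_2c	n_both
mouse1	A_caudal	42	36	3	3
mouse1	B_caudal	52	49	4	4
mouse1	C_caudal	48	47	2	2
mouse1	D_rostral	3	3	0	0
mouse1	E_rostral	4	4	0	0
mouse2	D_caudal	71	68	9	9
mouse2	B_medial	13	10	2	1
mouse2	C_medial	26	26	4	4
mouse2	A_rostral	3	3	0	0
mouse3	B_caudal	94	83	10	7
mouse3	D_caudal	85	76	5	5
mouse3	A_medial	70	62	2	1
mouse3	C_rostral	10	9	1	1
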