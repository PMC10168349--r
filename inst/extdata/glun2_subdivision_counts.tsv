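subdivision	mouse	n_tdt	n_2d	n_2c	n_both
central_nucleus	mouse1	89	84	5	5
central_nucleus	mouse2	68	67	12	12
central_nucleus	mouse3	199	175	14	11
dorsal_cortex	mouse1	47	42	4	4
dorsal_cortex	mouse2	28	25	1	1
dorsal_cortex	mouse3	38	36	2	2
lateral_cortex	mouse1	13	13	0	0
lateral_cortex	mouse2	17	15	2	1
lateral_cortex	mouse3	22	19	2	1
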