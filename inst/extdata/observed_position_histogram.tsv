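k	n_positions	sim_mean	sim_se
0	46	19.52	0.03
1	65	67.58	0.06
2	47	76.95	0.07
3	18	35.04	0.04
4	21	7.20	0.03
5	3	0.69	0.01
6	3	0.03	0.002
7	3	0.0002	0.0001
8	1	0.0	0.0
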