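subs	power
0	0
1	0
2	0
3	0
4	0.0811
6	0.381
8	0.45
10	0.4615
13	0.9167
16	0.96
20	1
25	1
30	1
37	1
40	1
60	1
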