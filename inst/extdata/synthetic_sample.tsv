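P1	P2	P3	P4	count
2	2	2	2	4
2	1	2	2	1
3	2	2	2	3
2	2	2	3	2
1	1	2	2	2
1	2	2	2	2
4	2	2	2	3
2	1	2	3	1
1	1	1	2	1
4	2	4	4	1
1	2	1	2	1
1	3	2	2	1
2	1	1	2	1
2	2	2	1	1
1	2	2	3	1
4	2	2	3	1
2	1	1	3	1
8	4	4	4	1
4	2	1	2	1
2	0	1	2	1
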