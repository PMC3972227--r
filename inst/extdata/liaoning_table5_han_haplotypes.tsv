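rank	A	B	DRB1	HF	LD
1	A*30	B*13	DRB1*07	4.88	4.7783
2	A*02	B*46	DRB1*09	2.38	2.0694
3	A*02	B*13	DRB1*12	1.61	1.1299
4	A*33	B*58	DRB1*03(17)	1.31	1.2988
5	A*33	B*58	DRB1*13	1.16	1.1402
6	A*02	B*46	DRB1*08	1.15	1.0114
7	A*33	B*44	DRB1*13	1.14	1.1166
8	A*02	B*40(61)	DRB1*09	0.91	0.5749
9	A*01	B*57	DRB1*07	0.80	0.7910
10	A*01	B*37	DRB1*10	0.79	0.7888
11	A*02	B*15(75)	DRB1*09	0.79	0.5964
12	A*02	B*15(62)	DRB1*15	0.78	0.3665
13	A*11	B*15(62)	DRB1*04	0.73	0.6115
14	A*11	B*15(75)	DRB1*12	0.68	0.5970
15	A*24	B*40(61)	DRB1*09	0.66	0.4968
16	A*33	B*44	DRB1*07	0.65	0.6068
17	A*24	B*54	DRB1*04	0.64	0.5885
18	A*11	B*13	DRB1*12	0.58	0.3473
19	A*02	B*40(61)	DRB1*15	0.55	0.1208
20	A*03	B*07	DRB1*15	0.55	0.5219
21	A*11	B*52	DRB1*15	0.53	0.4288
22	A*02	B*40(60)	DRB1*15	0.52	0.1570
23	A*24	B*40(61)	DRB1*15	0.51	0.3009
24	A*02	B*40(61)	DRB1*12	0.51	0.2135
25	A*02	B*51	DRB1*09	0.51	0.1971
26	A*02	B*15(75)	DRB1*15	0.49	0.2420
27	A*24	B*15(62)	DRB1*04	0.48	0.3609
28	A*11	B*13	DRB1*15	0.46	0.3069
29	A*32	B*52	DRB1*15	0.46	0.4598
30	A*02	B*15(75)	DRB1*12	0.46	0.2887
31	A*02	B*48	DRB1*09	0.44	0.2443
32	A*03	B*44	DRB1*13	0.43	0.4151
33	A*24	B*13	DRB1*12	0.42	0.1862
34	A*24	B*35	DRB1*15	0.41	0.2574
35	A*02	B*35	DRB1*15	0.41	0.0966
36	A*11	B*40(60)	DRB1*12	0.40	0.2785
37	A*24	B*15(62)	DRB1*15	0.40	0.1986
38	A*02	B*15(62)	DRB1*04	0.40	0.1555
39	A*02	B*15(62)	DRB1*12	0.39	0.1044
40	A*02	B*48	DRB1*15	0.39	0.1719
41	A*02	B*13	DRB1*07	0.38	-0.0865
42	A*11	B*40(60)	DRB1*09	0.38	0.2427
43	A*02	B*51	DRB1*14	0.37	0.2168
44	A*11	B*51	DRB1*09	0.36	0.2084
45	A*02	B*15(71)	DRB1*04	0.36	0.2949
46	A*24	B*46	DRB1*09	0.35	0.1987
47	A*11	B*40(60)	DRB1*15	0.35	0.1741
48	A*24	B*40(61)	DRB1*12	0.34	0.1956
49	A*02	B*50	DRB1*07	0.34	0.3054
50	A*02	B*46	DRB1*12	0.34	0.0651
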