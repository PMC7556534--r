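"age","qx"
20,0.00025393
21,0.000276458
22,0.000300985
23,0.000327687
24,0.000356758
25,0.000388409
26,0.000422868
27,0.000460383
28,0.000501227
29,0.000545694
30,0.000594107
31,0.000646814
32,0.000704198
33,0.000766672
34,0.000834689
35,0.00090874
36,0.000989361
37,0.00107713
38,0.00117269
39,0.00127673
40,0.00139
41,0.00151332
42,0.00164757
43,0.00179374
44,0.00195288
45,0.00212613
46,0.00231475
47,0.00252011
48,0.00274369
49,0.0029871
50,0.00325211
51,0.00354063
52,0.00385474
53,0.00419672
54,0.00456904
55,0.00497439
56,0.00541571
57,0.00589617
58,0.00641927
59,0.00698876
60,0.00760879
61,0.00828382
62,0.00901873
63,0.00981885
64,0.0106899
65,0.0116383
66,0.0126708
67,0.013795
68,0.0150188
69,0.0163512
70,0.0178019
71,0.0193812
72,0.0211006
73,0.0229726
74,0.0250107
75,0.0272296
76,0.0296453
77,0.0322753
78,0.0351387
79,0.0382561
80,0.0416501
81,0.0453452
82,0.0493681
83,0.0537479
84,0.0585162
85,0.0637076
86,0.0693595
87,0.0755129
88,0.0822122
89,0.0895058
90,0.0974465
91,0.106092
92,0.115504
93,0.125751
94,0.136907
95,0.149053
96,0.162277
97,0.176674
98,0.192348
99,0.209412
100,0.22799
101,0.248217
102,0.270238
103,0.294213
104,0.320315
105,0.348732
106,0.37967
107,0.413354
108,0.450025
109,0.48995
110,0.533417
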