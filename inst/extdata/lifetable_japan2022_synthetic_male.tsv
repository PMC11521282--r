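age	qx
65	0.01
66	0.0109451850387351
67	0.0119791657962791
68	0.0131101766581475
69	0.0143471942366893
70	0.0157
71	0.0172751251937495
72	0.0190067456642314
73	0.0209100857421139
74	0.0230017820876308
75	0.0253
76	0.0282073533391921
77	0.0314433826276748
78	0.0350439175491714
79	0.0390483678858939
80	0.0435
81	0.0491810474099879
82	0.0555822274783783
83	0.0627886875558261
84	0.0708939060347089
85	0.08
86	0.0902539844563982
87	0.101748022296058
88	0.114611384121525
89	0.128980975994028
90	0.145
91	0.160747136929276
92	0.178019476741935
93	0.196920541729801
94	0.21754994088574
95	0.24
96	0.261006509642949
97	0.283486530856307
98	0.307471183109296
99	0.33297649869831
100	0.36
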