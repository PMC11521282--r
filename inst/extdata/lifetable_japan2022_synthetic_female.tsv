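age	qx
65	0.004
66	0.00438059885915287
67	0.00479732429649093
68	0.00525358803741416
69	0.00575312052538668
70	0.00629999999999997
71	0.00700467158306561
72	0.00778785319937503
73	0.0086582187423131
74	0.00962538307656979
75	0.0107
76	0.0120670553103597
77	0.0136075641013572
78	0.0153432059902454
79	0.0172982806778884
80	0.0195
81	0.0226385545310284
82	0.0262754583179089
83	0.0304874627804754
84	0.0353623077296519
85	0.041
86	0.0480547496201356
87	0.0562873337760744
88	0.065880798300976
89	0.0770414872374064
90	0.09
91	0.103664790315598
92	0.119264799190246
93	0.137027479140078
94	0.157191233397603
95	0.18
96	0.19999700178059
97	0.221899945433514
98	0.245812388558762
99	0.271823158448651
100	0.3
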