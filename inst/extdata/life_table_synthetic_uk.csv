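age,q,copd_fraction
40,0.0011992803,0.05
41,0.0013095276,0.05
42,0.0014299024,0.05
43,0.0015613337,0.05
44,0.0017048353,0.05
45,0.0018615139,0.05
46,0.0020325769,0.05
47,0.0022193422,0.05
48,0.0024232478,0.05
49,0.0026458627,0.05
50,0.0028888987,0.05
51,0.0031542236,0.05
52,0.0034438745,0.05
53,0.0037600737,0.05
54,0.004105245,0.05
55,0.0044820312,0.05
56,0.0048933146,0.05
57,0.005342237,0.05
58,0.0058322236,0.05
59,0.0063670075,0.05
60,0.0069506565,0.05
61,0.0075876028,0.05
62,0.0082826739,0.05
63,0.0090411273,0.05
64,0.0098686869,0.05
65,0.010771583,0.05
66,0.011756594,0.05
67,0.012831094,0.05
68,0.014003101,0.05
69,0.01528133,0.05
70,0.016675247,0.05
71,0.018195135,0.05
72,0.019852151,0.05
73,0.021658399,0.05
74,0.023626999,0.05
75,0.025772162,0.05
76,0.028109272,0.05
77,0.030654964,0.05
78,0.033427215,0.05
79,0.036445424,0.05
80,0.039730509,0.05
81,0.043304991,0.05
82,0.047193087,0.05
83,0.051420796,0.05
84,0.056015979,0.05
85,0.061008443,0.05
86,0.06643,0.05
87,0.072314528,0.05
88,0.078698004,0.05
89,0.085618522,0.05
90,0.093116282,0.05
91,0.10123354,0.05
92,0.11001453,0.05
93,0.1195053,0.05
94,0.12975354,0.05
95,0.14080831,0.05
96,0.15271964,0.05
97,0.16553814,0.05
98,0.17931438,0.05
99,0.19409823,0.05
100,0.209938,0.05
101,0.22687945,0.05
102,0.24496464,0.05
103,0.26423058,0.05
104,0.28470769,0.05
105,0.30641807,0.05
106,0.32937359,0.05
107,0.35357383,0.05
108,0.37900383,0.05
109,0.4056318,0.05
110,1,0.05
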