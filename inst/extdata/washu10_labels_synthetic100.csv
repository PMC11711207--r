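node_id,network
1,FPN
2,SUB
3,AUD
4,VAN
5,CO
6,unassigned
7,FPN
8,AUD
9,SUB
10,DAN
11,VIS
12,AUD
13,AUD
14,SMN
15,VIS
16,AUD
17,DMN
18,SMN
19,DMN
20,DAN
21,SAL
22,VIS
23,unassigned
24,DMN
25,VIS
26,CO
27,AUD
28,VAN
29,SMN
30,DAN
31,SUB
32,unassigned
33,SMN
34,FPN
35,unassigned
36,DAN
37,SUB
38,SMN
39,SAL
40,SMN
41,FPN
42,VAN
43,FPN
44,AUD
45,SAL
46,SAL
47,VIS
48,CO
49,VIS
50,DAN
51,DMN
52,SUB
53,VIS
54,unassigned
55,VIS
56,VAN
57,SMN
58,DMN
59,CO
60,unassigned
61,VIS
62,DMN
63,VAN
64,CO
65,DMN
66,FPN
67,unassigned
68,SAL
69,SUB
70,VAN
71,CO
72,DMN
73,FPN
74,CO
75,SUB
76,AUD
77,unassigned
78,SAL
79,SUB
80,unassigned
81,SMN
82,FPN
83,VAN
84,CO
85,DAN
86,SAL
87,SAL
88,VAN
89,FPN
90,SMN
91,SAL
92,AUD
93,DAN
94,VAN
95,DAN
96,CO
97,SUB
98,DMN
99,DAN
100,unassigned
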