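item,facet,reverse
1,O,FALSE
2,D,FALSE
3,NJ,TRUE
4,NR,FALSE
5,AA,TRUE
6,O,FALSE
7,D,FALSE
8,AA,TRUE
9,NR,FALSE
10,NJ,TRUE
11,O,FALSE
12,D,TRUE
13,AA,TRUE
14,NJ,TRUE
15,O,FALSE
16,D,TRUE
17,NJ,TRUE
18,AA,TRUE
19,NR,FALSE
20,O,FALSE
21,NR,FALSE
22,D,TRUE
23,AA,TRUE
24,NR,FALSE
25,NJ,TRUE
26,O,FALSE
27,D,FALSE
28,AA,TRUE
29,NR,FALSE
30,NJ,TRUE
31,O,FALSE
32,D,FALSE
33,NR,FALSE
34,AA,TRUE
35,NJ,TRUE
36,O,FALSE
37,D,FALSE
38,AA,TRUE
39,NJ,TRUE
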