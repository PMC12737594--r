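dyad_id,category,test_class
1,Yes,U
2,No,U
3,Yes,S
4,No,U
5,No,U
6,Yes,U
7,No,U
8,Yes,U
9,No,U
10,Maybe,U
11,No,U
12,No,P
13,Yes after a training programme,U
14,No,U
15,Yes after a training programme,P
16,Maybe,U
17,Yes,S
18,Yes,S
19,No,U
20,Yes,U
21,Yes,S
22,Yes,S
23,Yes,U
24,Yes,S
25,Yes,U
26,Yes,U
27,Yes,U
28,Yes,S
29,Yes,S
30,Yes,U
31,No,U
32,Maybe,U
33,No,U
34,Yes,P
35,Yes,U
36,Yes,S
37,Yes,P
38,Yes,P
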