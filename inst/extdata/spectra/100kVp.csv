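energy_keV,weight
10,6.52966e-22
11,2.79682e-16
12,2.04876e-12
13,1.11368e-09
14,1.07974e-07
15,3.222e-06
16,4.2053e-05
17,0.00030311
18,0.00141415
19,0.00477006
20,0.0125847
21,0.0274902
22,0.0518467
23,0.0871065
24,0.133488
25,0.190003
26,0.25474
27,0.32525
28,0.398915
29,0.473238
30,0.546034
31,0.615523
32,0.680353
33,0.739582
34,0.792627
35,0.839203
36,0.879264
37,0.91294
38,0.940493
39,0.962271
40,0.978677
41,0.990141
42,0.997104
43,1
44,0.99925
45,0.995251
46,0.988377
47,0.978972
48,0.967354
49,0.953811
50,0.938604
51,0.921971
52,0.904122
53,0.885248
54,0.865517
55,0.845078
56,0.824066
57,0.802598
58,0.780778
59,0.758698
60,0.736436
61,0.714065
62,0.691645
63,0.669231
64,0.646867
65,0.624596
66,0.602451
67,0.580462
68,0.558656
69,0.537053
70,0.515672
71,0.494528
72,0.473635
73,0.453002
74,0.432638
75,0.41255
76,0.392742
77,0.373218
78,0.353981
79,0.335031
80,0.31637
81,0.297997
82,0.279911
83,0.26211
84,0.244593
85,0.227356
86,0.210397
87,0.193713
88,0.177299
89,0.161153
90,0.145271
91,0.129647
92,0.114279
93,0.0991618
94,0.0842911
95,0.0696627
96,0.0552721
97,0.0411149
98,0.0271867
99,0.0134832
100,0
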