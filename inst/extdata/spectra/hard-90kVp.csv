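energy_keV,weight
10,7.03371e-22
11,3.00849e-16
12,2.20064e-12
13,1.19448e-09
14,1.15633e-07
15,3.4452e-06
16,4.48948e-05
17,0.000323066
18,0.00150473
19,0.00506691
20,0.0133443
21,0.0290969
22,0.0547749
23,0.0918504
24,0.140481
25,0.199553
26,0.266988
27,0.340159
28,0.41628
29,0.492717
30,0.567178
31,0.637813
32,0.703234
33,0.762487
34,0.815003
35,0.860524
36,0.899041
37,0.930731
38,0.955903
39,0.974954
40,0.988335
41,0.996523
42,1
43,0.999239
44,0.994696
45,0.986799
46,0.975951
47,0.962519
48,0.946842
49,0.929228
50,0.909953
51,0.889267
52,0.867393
53,0.84453
54,0.820855
55,0.796524
56,0.771676
57,0.746432
58,0.7209
59,0.695173
60,0.669334
61,0.643454
62,0.617596
63,0.591813
64,0.566151
65,0.540651
66,0.515348
67,0.490269
68,0.46544
69,0.440881
70,0.416609
71,0.392639
72,0.368982
73,0.345646
74,0.32264
75,0.299968
76,0.277633
77,0.255637
78,0.233983
79,0.212669
80,0.191695
81,0.171059
82,0.150759
83,0.130791
84,0.111153
85,0.0918399
86,0.072848
87,0.0541729
88,0.0358098
89,0.0177539
90,0
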