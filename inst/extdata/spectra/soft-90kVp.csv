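energy_keV,weight
10,2.08582e-08
11,2.8594e-06
12,8.23847e-05
13,0.00087657
14,0.00482275
15,0.0169157
16,0.0432807
17,0.0883299
18,0.152803
19,0.233747
20,0.325836
21,0.422985
22,0.519586
23,0.611172
24,0.694618
25,0.768045
26,0.830595
27,0.882169
28,0.923184
29,0.954383
30,0.976681
31,0.991067
32,0.998526
33,1
34,0.996361
35,0.988399
36,0.976818
37,0.962236
38,0.945195
39,0.926159
40,0.905532
41,0.883656
42,0.860824
43,0.837282
44,0.81324
45,0.788873
46,0.764329
47,0.739731
48,0.71518
49,0.690761
50,0.666543
51,0.642581
52,0.618923
53,0.595602
54,0.572649
55,0.550085
56,0.527926
57,0.506184
58,0.484867
59,0.46398
60,0.443524
61,0.423499
62,0.403903
63,0.384732
64,0.365981
65,0.347644
66,0.329714
67,0.312184
68,0.295046
69,0.278292
70,0.261913
71,0.245901
72,0.230246
73,0.21494
74,0.199974
75,0.185339
76,0.171026
77,0.157028
78,0.143335
79,0.129939
80,0.116832
81,0.104006
82,0.091453
83,0.079166
84,0.0671373
85,0.0553597
86,0.0438261
87,0.0325299
88,0.0214644
89,0.0106231
90,0
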