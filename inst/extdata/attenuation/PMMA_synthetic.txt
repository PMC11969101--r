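# material: PMMA (polymethyl methacrylate, C5H8O2)
# density_g_cm3: 1.19
# nominal_z: 6.5
# source: synthetic mixture rule over the corrected-model H/C/O tables, mass fractions H 0.0805 C 0.5998 O 0.3196
# grid: 1 keV, 10-150 keV, densified by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 3.95913
11 3.06821
12 2.43115
13 1.9626
14 1.60971
15 1.33845
16 1.14799
17 0.993839
18 0.867509
19 0.762826
20 0.675214
21 0.618477
22 0.568826
23 0.52511
24 0.486407
25 0.451967
26 0.421178
27 0.393532
28 0.36861
29 0.34606
30 0.325586
31 0.314551
32 0.304223
33 0.294536
34 0.285434
35 0.276865
36 0.268783
37 0.26115
38 0.253928
39 0.247086
40 0.240595
41 0.23684
42 0.233232
43 0.229762
44 0.226422
45 0.223204
46 0.2201
47 0.217105
48 0.214213
49 0.211418
50 0.208715
51 0.206891
52 0.205118
53 0.203394
54 0.201716
55 0.200082
56 0.198491
57 0.19694
58 0.195428
59 0.193953
60 0.192514
61 0.191454
62 0.190418
63 0.189404
64 0.188411
65 0.187438
66 0.186485
67 0.185551
68 0.184636
69 0.183738
70 0.182858
71 0.181994
72 0.181147
73 0.180314
74 0.179497
75 0.178695
76 0.177906
77 0.177132
78 0.176371
79 0.175622
80 0.174886
81 0.174257
82 0.173637
83 0.173027
84 0.172426
85 0.171835
86 0.171252
87 0.170678
88 0.170113
89 0.169556
90 0.169007
91 0.168465
92 0.167931
93 0.167405
94 0.166886
95 0.166374
96 0.165869
97 0.165371
98 0.164879
99 0.164394
100 0.163915
101 0.163438
102 0.162967
103 0.162503
104 0.162044
105 0.161591
106 0.161143
107 0.160701
108 0.160264
109 0.159832
110 0.159406
111 0.158984
112 0.158567
113 0.158155
114 0.157748
115 0.157345
116 0.156947
117 0.156553
118 0.156164
119 0.155779
120 0.155397
121 0.155021
122 0.154648
123 0.154279
124 0.153913
125 0.153552
126 0.153194
127 0.15284
128 0.15249
129 0.152143
130 0.151799
131 0.151459
132 0.151123
133 0.150789
134 0.150459
135 0.150132
136 0.149808
137 0.149487
138 0.149169
139 0.148854
140 0.148543
141 0.148233
142 0.147927
143 0.147624
144 0.147323
145 0.147025
146 0.146729
147 0.146437
148 0.146146
149 0.145859
150 0.145573
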