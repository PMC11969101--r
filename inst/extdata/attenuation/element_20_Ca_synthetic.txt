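# material: Ca (element Z=20, A=40.078)
# nominal_z: 20
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 95.8904
11 72.2202
12 55.7522
13 43.9407
14 35.2483
15 28.7089
16 23.6757
17 19.7545
18 16.6542
19 14.1707
20 12.1579
21 10.5375
22 9.19408
23 8.0707
24 7.124
25 6.32046
26 5.63394
27 5.04383
28 4.53374
29 4.09052
30 3.70351
31 3.37971
32 3.09318
33 2.83868
34 2.6118
35 2.40887
36 2.22677
37 2.06288
38 1.91495
39 1.78106
40 1.65958
41 1.55682
42 1.46267
43 1.37623
44 1.29672
45 1.22344
46 1.15577
47 1.09318
48 1.0352
49 0.981392
50 0.931386
51 0.889261
52 0.849804
53 0.812801
54 0.778056
55 0.745393
56 0.714654
57 0.685694
58 0.65838
59 0.632594
60 0.608226
61 0.58893
62 0.570546
63 0.553015
64 0.536287
65 0.520313
66 0.505047
67 0.490449
68 0.47648
69 0.463104
70 0.450288
71 0.438001
72 0.426215
73 0.414901
74 0.404036
75 0.393595
76 0.383557
77 0.373902
78 0.364609
79 0.355662
80 0.347042
81 0.340695
82 0.33454
83 0.328569
84 0.322774
85 0.317148
86 0.311684
87 0.306376
88 0.301217
89 0.296202
90 0.291325
91 0.286582
92 0.281965
93 0.277472
94 0.273098
95 0.268837
96 0.264687
97 0.260643
98 0.256701
99 0.252858
100 0.24911
101 0.246649
102 0.244237
103 0.241872
104 0.239552
105 0.237276
106 0.235043
107 0.232851
108 0.2307
109 0.228589
110 0.226516
111 0.22448
112 0.222481
113 0.220517
114 0.218587
115 0.216691
116 0.214827
117 0.212996
118 0.211195
119 0.209425
120 0.207684
121 0.205971
122 0.204287
123 0.20263
124 0.201
125 0.199396
126 0.197817
127 0.196263
128 0.194734
129 0.193228
130 0.191745
131 0.190285
132 0.188847
133 0.18743
134 0.186035
135 0.18466
136 0.183306
137 0.181971
138 0.180656
139 0.179359
140 0.178081
141 0.176821
142 0.175579
143 0.174354
144 0.173146
145 0.171955
146 0.17078
147 0.169621
148 0.168478
149 0.16735
150 0.166237
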