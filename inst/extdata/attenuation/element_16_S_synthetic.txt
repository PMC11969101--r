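# material: S (element Z=16, A=32.060)
# nominal_z: 16
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 49.858
11 37.5925
12 29.0499
13 22.9169
14 18.3993
15 14.9979
16 12.3903
17 10.3553
18 8.74374
19 7.45086
20 6.40149
21 5.56703
22 4.87292
23 4.29068
24 3.79852
25 3.37959
26 3.02068
27 2.71134
28 2.44327
29 2.20976
30 2.00539
31 1.83999
32 1.69286
33 1.56149
34 1.44379
35 1.338
36 1.24262
37 1.15639
38 1.0782
39 1.00713
40 0.942371
41 0.89014
42 0.84196
43 0.797432
44 0.756202
45 0.71796
46 0.682431
47 0.649367
48 0.618553
49 0.589791
50 0.562908
51 0.541447
52 0.521198
53 0.50207
54 0.483983
55 0.466861
56 0.450638
57 0.43525
58 0.420642
59 0.406762
60 0.393562
61 0.383835
62 0.374501
63 0.365538
64 0.356925
65 0.348645
66 0.340678
67 0.33301
68 0.325623
69 0.318505
70 0.311642
71 0.305021
72 0.29863
73 0.292458
74 0.286495
75 0.280732
76 0.275158
77 0.269766
78 0.264547
79 0.259494
80 0.254599
81 0.251234
82 0.247954
83 0.244756
84 0.241637
85 0.238594
86 0.235624
87 0.232724
88 0.229893
89 0.227128
90 0.224426
91 0.221786
92 0.219205
93 0.216682
94 0.214214
95 0.2118
96 0.209438
97 0.207127
98 0.204864
99 0.202649
100 0.200479
101 0.199073
102 0.197691
103 0.196332
104 0.194995
105 0.19368
106 0.192386
107 0.191112
108 0.189859
109 0.188626
110 0.187411
111 0.186216
112 0.185038
113 0.183879
114 0.182736
115 0.181611
116 0.180502
117 0.17941
118 0.178333
119 0.177272
120 0.176226
121 0.175195
122 0.174178
123 0.173175
124 0.172187
125 0.171211
126 0.170249
127 0.1693
128 0.168363
129 0.167439
130 0.166527
131 0.165627
132 0.164739
133 0.163862
134 0.162996
135 0.162141
136 0.161297
137 0.160464
138 0.159641
139 0.158827
140 0.158024
141 0.157231
142 0.156447
143 0.155672
144 0.154907
145 0.154151
146 0.153403
147 0.152665
148 0.151934
149 0.151212
150 0.150499
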