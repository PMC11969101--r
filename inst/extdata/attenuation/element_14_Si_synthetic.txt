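# material: Si (element Z=14, A=28.086)
# nominal_z: 14
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 33.6947
11 25.4334
12 19.6737
13 15.5345
14 12.4829
15 10.1833
16 8.4273
17 7.05461
18 5.96584
19 5.09106
20 4.38003
21 3.82123
22 3.35496
23 2.96267
24 2.63014
25 2.34631
26 2.1025
27 1.89185
28 1.70885
29 1.54908
30 1.40892
31 1.29889
32 1.20055
33 1.11234
34 1.03297
35 0.961323
36 0.896458
37 0.837572
38 0.783973
39 0.735065
40 0.690334
41 0.655661
42 0.623503
43 0.593624
44 0.565816
45 0.539892
46 0.515687
47 0.493054
48 0.471859
49 0.451985
50 0.433325
51 0.419002
52 0.405417
53 0.392518
54 0.38026
55 0.3686
56 0.357497
57 0.346917
58 0.336825
59 0.327192
60 0.31799
61 0.311488
62 0.305221
63 0.299178
64 0.293347
65 0.287717
66 0.282279
67 0.277023
68 0.27194
69 0.267023
70 0.262264
71 0.257656
72 0.253191
73 0.248863
74 0.244667
75 0.240596
76 0.236646
77 0.232811
78 0.229086
79 0.225468
80 0.221951
81 0.219594
82 0.217291
83 0.215039
84 0.212838
85 0.210684
86 0.208577
87 0.206516
88 0.204497
89 0.202521
90 0.200586
91 0.19869
92 0.196833
93 0.195013
94 0.193229
95 0.19148
96 0.189765
97 0.188082
98 0.186432
99 0.184813
100 0.183223
101 0.182169
102 0.18113
103 0.180107
104 0.179101
105 0.178109
106 0.177132
107 0.176169
108 0.175221
109 0.174286
110 0.173365
111 0.172457
112 0.171562
113 0.170679
114 0.169809
115 0.16895
116 0.168104
117 0.167268
118 0.166444
119 0.165631
120 0.164829
121 0.164037
122 0.163256
123 0.162484
124 0.161722
125 0.16097
126 0.160228
127 0.159494
128 0.15877
129 0.158055
130 0.157348
131 0.15665
132 0.15596
133 0.155279
134 0.154605
135 0.15394
136 0.153282
137 0.152632
138 0.151989
139 0.151353
140 0.150725
141 0.150104
142 0.14949
143 0.148882
144 0.148281
145 0.147687
146 0.147099
147 0.146518
148 0.145942
149 0.145373
150 0.14481
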