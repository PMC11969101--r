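# material: Cl (element Z=17, A=35.450)
# nominal_z: 17
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 57.218
11 43.1256
12 33.3142
13 26.2726
14 21.0874
15 17.1843
16 14.1881
17 11.8513
18 10.0017
19 8.51854
20 7.31534
21 6.35463
22 5.55637
23 4.88747
24 4.32263
25 3.84228
26 3.43113
27 3.0771
28 2.77054
29 2.50373
30 2.2704
31 2.07949
32 1.90995
33 1.75883
34 1.62365
35 1.50235
36 1.39315
37 1.29456
38 1.20531
39 1.12429
40 1.05057
41 0.990205
42 0.934638
43 0.88339
44 0.836034
45 0.792198
46 0.751549
47 0.713794
48 0.678672
49 0.64595
50 0.61542
51 0.590647
52 0.567324
53 0.54534
54 0.524596
55 0.505
56 0.486469
57 0.468929
58 0.45231
59 0.436549
60 0.421588
61 0.410342
62 0.399571
63 0.389249
64 0.37935
65 0.36985
66 0.360728
67 0.351963
68 0.343536
69 0.335429
70 0.327627
71 0.320112
72 0.312872
73 0.305892
74 0.299159
75 0.292662
76 0.28639
77 0.280331
78 0.274476
79 0.268816
80 0.263341
81 0.259516
82 0.255792
83 0.252166
84 0.248634
85 0.245193
86 0.241838
87 0.238567
88 0.235378
89 0.232266
90 0.229229
91 0.226265
92 0.223371
93 0.220545
94 0.217784
95 0.215087
96 0.21245
97 0.209873
98 0.207353
99 0.204888
100 0.202477
101 0.200919
102 0.199388
103 0.197884
104 0.196405
105 0.194951
106 0.193522
107 0.192116
108 0.190734
109 0.189374
110 0.188036
111 0.18672
112 0.185424
113 0.184149
114 0.182894
115 0.181658
116 0.180441
117 0.179242
118 0.178062
119 0.176899
120 0.175754
121 0.174625
122 0.173513
123 0.172417
124 0.171336
125 0.170271
126 0.169221
127 0.168186
128 0.167165
129 0.166158
130 0.165165
131 0.164185
132 0.163219
133 0.162265
134 0.161324
135 0.160396
136 0.15948
137 0.158575
138 0.157682
139 0.156801
140 0.155931
141 0.155071
142 0.154223
143 0.153385
144 0.152558
145 0.15174
146 0.150933
147 0.150135
148 0.149347
149 0.148568
150 0.147799
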