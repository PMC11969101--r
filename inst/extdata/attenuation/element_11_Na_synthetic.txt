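# material: Na (element Z=11, A=22.990)
# nominal_z: 11
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 16.0146
11 12.1298
12 9.4123
13 7.45352
14 6.00538
15 4.91128
16 4.08577
17 3.43715
18 2.92022
19 2.50301
20 2.16243
21 1.90374
22 1.68596
23 1.50118
24 1.34327
25 1.20744
26 1.08989
27 0.987598
28 0.898119
29 0.819474
30 0.750042
31 0.699801
32 0.654364
33 0.613142
34 0.575635
35 0.541411
36 0.510103
37 0.48139
38 0.454996
39 0.430679
40 0.408229
41 0.39235
42 0.377449
43 0.363446
44 0.350266
45 0.337844
46 0.326122
47 0.315045
48 0.304567
49 0.294642
50 0.285231
51 0.27852
52 0.272093
53 0.265932
54 0.260022
55 0.254348
56 0.248897
57 0.243656
58 0.238614
59 0.23376
60 0.229084
61 0.22595
62 0.222909
63 0.219956
64 0.217088
65 0.214302
66 0.211592
67 0.208957
68 0.206393
69 0.203898
70 0.201467
71 0.1991
72 0.196793
73 0.194544
74 0.19235
75 0.190211
76 0.188123
77 0.186084
78 0.184094
79 0.18215
80 0.180251
81 0.178972
82 0.177719
83 0.176489
84 0.175282
85 0.174097
86 0.172935
87 0.171793
88 0.170672
89 0.16957
90 0.168488
91 0.167425
92 0.16638
93 0.165352
94 0.164342
95 0.163349
96 0.162372
97 0.161411
98 0.160465
99 0.159534
100 0.158618
101 0.157946
102 0.157283
103 0.15663
104 0.155985
105 0.15535
106 0.154722
107 0.154104
108 0.153493
109 0.15289
110 0.152296
111 0.151709
112 0.151129
113 0.150557
114 0.149992
115 0.149434
116 0.148883
117 0.148338
118 0.1478
119 0.147269
120 0.146744
121 0.146225
122 0.145712
123 0.145206
124 0.144705
125 0.144209
126 0.14372
127 0.143236
128 0.142757
129 0.142284
130 0.141816
131 0.141353
132 0.140895
133 0.140442
134 0.139993
135 0.13955
136 0.139111
137 0.138677
138 0.138247
139 0.137822
140 0.137401
141 0.136984
142 0.136571
143 0.136163
144 0.135759
145 0.135358
146 0.134962
147 0.134569
148 0.13418
149 0.133795
150 0.133414
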