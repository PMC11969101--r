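# material: C (element Z=6, A=12.011)
# nominal_z: 6
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 2.98114
11 2.325
12 1.85296
13 1.50383
14 1.23953
15 1.0354
16 0.894571
17 0.779779
18 0.685076
19 0.606104
20 0.539616
21 0.497846
22 0.461034
23 0.428404
24 0.39933
25 0.373299
26 0.349888
27 0.328748
28 0.309587
29 0.292157
30 0.276251
31 0.268061
32 0.260363
33 0.253113
34 0.246272
35 0.239806
36 0.233685
37 0.227882
38 0.222372
39 0.217134
40 0.212146
41 0.209306
42 0.20657
43 0.203934
44 0.20139
45 0.198934
46 0.196562
47 0.194267
48 0.192047
49 0.189897
50 0.187815
51 0.18639
52 0.185004
53 0.183654
54 0.182339
55 0.181057
56 0.179807
57 0.178588
58 0.177398
59 0.176236
60 0.175101
61 0.174233
62 0.173384
63 0.172552
64 0.171737
65 0.170938
66 0.170156
67 0.169388
68 0.168636
69 0.167897
70 0.167173
71 0.166461
72 0.165763
73 0.165077
74 0.164403
75 0.163741
76 0.163091
77 0.162451
78 0.161822
79 0.161204
80 0.160596
81 0.160051
82 0.159515
83 0.158987
84 0.158467
85 0.157954
86 0.15745
87 0.156953
88 0.156463
89 0.15598
90 0.155504
91 0.155035
92 0.154572
93 0.154116
94 0.153666
95 0.153221
96 0.152783
97 0.152351
98 0.151924
99 0.151503
100 0.151087
101 0.150659
102 0.150236
103 0.149819
104 0.149406
105 0.148999
106 0.148597
107 0.1482
108 0.147807
109 0.147419
110 0.147036
111 0.146657
112 0.146282
113 0.145912
114 0.145546
115 0.145184
116 0.144826
117 0.144471
118 0.144121
119 0.143775
120 0.143432
121 0.143093
122 0.142758
123 0.142426
124 0.142097
125 0.141772
126 0.14145
127 0.141132
128 0.140817
129 0.140504
130 0.140195
131 0.139889
132 0.139586
133 0.139286
134 0.138989
135 0.138695
136 0.138403
137 0.138114
138 0.137828
139 0.137545
140 0.137264
141 0.136985
142 0.13671
143 0.136436
144 0.136165
145 0.135897
146 0.135631
147 0.135367
148 0.135106
149 0.134847
150 0.13459
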