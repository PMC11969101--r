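# material: B (element Z=5, A=10.811)
# nominal_z: 5
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 1.69207
11 1.34662
12 1.09322
13 0.902449
14 0.755634
15 0.640505
16 0.56495
17 0.502115
18 0.449288
19 0.404442
20 0.366043
21 0.343601
22 0.323486
23 0.305367
24 0.288971
25 0.274072
26 0.260481
27 0.24804
28 0.236614
29 0.226089
30 0.216365
31 0.211844
32 0.207556
33 0.203483
34 0.199608
35 0.195916
36 0.192394
37 0.189029
38 0.18581
39 0.182727
40 0.179772
41 0.178114
42 0.176511
43 0.17496
44 0.173458
45 0.172001
46 0.170589
47 0.169218
48 0.167887
49 0.166593
50 0.165336
51 0.164424
52 0.163536
53 0.162669
54 0.161822
55 0.160996
56 0.160188
57 0.159399
58 0.158627
59 0.157872
60 0.157133
61 0.156505
62 0.155888
63 0.155284
64 0.154692
65 0.154111
66 0.153541
67 0.152982
68 0.152433
69 0.151894
70 0.151365
71 0.150845
72 0.150334
73 0.149832
74 0.149338
75 0.148852
76 0.148375
77 0.147905
78 0.147442
79 0.146987
80 0.14654
81 0.146095
82 0.145657
83 0.145225
84 0.1448
85 0.144382
86 0.143969
87 0.143562
88 0.143161
89 0.142766
90 0.142376
91 0.141992
92 0.141613
93 0.141238
94 0.140869
95 0.140505
96 0.140145
97 0.13979
98 0.13944
99 0.139094
100 0.138752
101 0.138377
102 0.138006
103 0.13764
104 0.137278
105 0.13692
106 0.136567
107 0.136218
108 0.135874
109 0.135533
110 0.135196
111 0.134863
112 0.134534
113 0.134209
114 0.133887
115 0.133569
116 0.133254
117 0.132943
118 0.132635
119 0.13233
120 0.132029
121 0.131731
122 0.131436
123 0.131144
124 0.130855
125 0.130569
126 0.130286
127 0.130005
128 0.129728
129 0.129453
130 0.129181
131 0.128912
132 0.128645
133 0.128381
134 0.128119
135 0.12786
136 0.127603
137 0.127349
138 0.127096
139 0.126847
140 0.126599
141 0.126354
142 0.126111
143 0.12587
144 0.125631
145 0.125395
146 0.12516
147 0.124928
148 0.124697
149 0.124469
150 0.124242
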