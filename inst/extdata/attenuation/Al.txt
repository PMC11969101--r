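# material: Al (aluminium)
# density_g_cm3: 2.699
# nominal_z: 13
# source: canonical reference mass-attenuation values on the standard 10-point grid
# grid: 1 keV, 10-150 keV, densified by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 26.23
11 19.8152
12 15.3392
13 12.1203
14 9.7456
15 7.955
16 6.59159
17 5.52449
18 4.67713
19 3.99556
20 3.441
21 3.00884
22 2.64744
23 2.34273
24 2.08392
25 1.86257
26 1.67209
27 1.50721
28 1.36373
29 1.23825
30 1.128
31 1.04326
32 0.967276
33 0.898918
34 0.837221
35 0.781368
36 0.73066
37 0.684501
38 0.642375
39 0.603836
40 0.5685
41 0.541804
42 0.51696
43 0.493801
44 0.472177
45 0.451954
46 0.433013
47 0.415249
48 0.398564
49 0.382874
50 0.3681
51 0.357018
52 0.346474
53 0.336435
54 0.326865
55 0.317737
56 0.30902
57 0.300691
58 0.292726
59 0.285102
60 0.2778
61 0.272745
62 0.267862
63 0.263142
64 0.258578
65 0.254162
66 0.249887
67 0.245747
68 0.241735
69 0.237845
70 0.234073
71 0.230413
72 0.226861
73 0.223411
74 0.220059
75 0.216801
76 0.213634
77 0.210554
78 0.207557
79 0.20464
80 0.2018
81 0.199909
82 0.198058
83 0.196247
84 0.194474
85 0.192737
86 0.191036
87 0.18937
88 0.187736
89 0.186135
90 0.184566
91 0.183026
92 0.181516
93 0.180035
94 0.178582
95 0.177155
96 0.175755
97 0.17438
98 0.173029
99 0.171703
100 0.1704
101 0.169514
102 0.168642
103 0.167782
104 0.166936
105 0.166101
106 0.165279
107 0.164468
108 0.163669
109 0.16288
110 0.162103
111 0.161337
112 0.160581
113 0.159835
114 0.159099
115 0.158373
116 0.157657
117 0.15695
118 0.156252
119 0.155563
120 0.154882
121 0.154211
122 0.153547
123 0.152892
124 0.152245
125 0.151606
126 0.150975
127 0.150351
128 0.149735
129 0.149126
130 0.148524
131 0.147929
132 0.147341
133 0.14676
134 0.146185
135 0.145617
136 0.145056
137 0.1445
138 0.143951
139 0.143407
140 0.14287
141 0.142338
142 0.141813
143 0.141292
144 0.140778
145 0.140268
146 0.139764
147 0.139266
148 0.138772
149 0.138284
150 0.1378
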