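# material: N (element Z=7, A=14.007)
# nominal_z: 7
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 4.57696
11 3.52714
12 2.7805
13 2.23406
14 1.82437
15 1.51079
16 1.28696
17 1.107
18 0.960449
19 0.83972
20 0.739245
21 0.672132
22 0.613825
23 0.562842
24 0.518002
25 0.478353
26 0.44312
27 0.41167
28 0.383477
29 0.358106
30 0.33519
31 0.322218
32 0.310135
33 0.298858
34 0.288308
35 0.278422
36 0.269138
37 0.260406
38 0.252179
39 0.244416
40 0.23708
41 0.232744
42 0.228589
43 0.224604
44 0.220777
45 0.217099
46 0.213562
47 0.210156
48 0.206875
49 0.203711
50 0.200657
51 0.198614
52 0.19663
53 0.194704
54 0.192831
55 0.191011
56 0.18924
57 0.187517
58 0.185839
59 0.184204
60 0.18261
61 0.181477
62 0.18037
63 0.179287
64 0.178227
65 0.177189
66 0.176174
67 0.175179
68 0.174205
69 0.17325
70 0.172314
71 0.171396
72 0.170496
73 0.169613
74 0.168746
75 0.167896
76 0.16706
77 0.16624
78 0.165435
79 0.164643
80 0.163865
81 0.163231
82 0.162606
83 0.161992
84 0.161387
85 0.160792
86 0.160206
87 0.159628
88 0.15906
89 0.158499
90 0.157947
91 0.157403
92 0.156867
93 0.156338
94 0.155817
95 0.155303
96 0.154796
97 0.154295
98 0.153802
99 0.153315
100 0.152835
101 0.152375
102 0.151922
103 0.151474
104 0.151032
105 0.150595
106 0.150164
107 0.149738
108 0.149317
109 0.148901
110 0.148491
111 0.148085
112 0.147683
113 0.147287
114 0.146895
115 0.146507
116 0.146124
117 0.145745
118 0.14537
119 0.144999
120 0.144633
121 0.14427
122 0.143911
123 0.143556
124 0.143205
125 0.142858
126 0.142514
127 0.142173
128 0.141836
129 0.141503
130 0.141172
131 0.140846
132 0.140522
133 0.140201
134 0.139884
135 0.13957
136 0.139259
137 0.13895
138 0.138645
139 0.138342
140 0.138043
141 0.137746
142 0.137451
143 0.13716
144 0.136871
145 0.136585
146 0.136301
147 0.13602
148 0.135741
149 0.135465
150 0.135191
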