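# material: P (element Z=15, A=30.974)
# nominal_z: 15
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 40.0529
11 30.214
12 23.3583
13 18.4343
14 14.8059
15 12.073
16 9.98141
17 8.34796
18 7.05353
19 6.01436
20 5.1704
21 4.50274
22 3.94661
23 3.4795
24 3.08417
25 2.74725
26 2.45827
27 2.20893
28 1.99261
29 1.804
30 1.63875
31 1.50682
32 1.3892
33 1.28398
34 1.18952
35 1.10445
36 1.02761
37 0.958007
38 0.894792
39 0.837231
40 0.784693
41 0.74308
42 0.704597
43 0.668945
44 0.635855
45 0.605091
46 0.576444
47 0.549726
48 0.52477
49 0.501428
50 0.479564
51 0.462431
52 0.446224
53 0.430878
54 0.416332
55 0.402531
56 0.389424
57 0.376964
58 0.36511
59 0.353821
60 0.343063
61 0.335299
62 0.327833
63 0.320648
64 0.313731
65 0.307066
66 0.300642
67 0.294446
68 0.288466
69 0.282692
70 0.277115
71 0.271725
72 0.266512
73 0.261469
74 0.256589
75 0.251863
76 0.247285
77 0.242849
78 0.238548
79 0.234376
80 0.230329
81 0.227586
82 0.224909
83 0.222296
84 0.219744
85 0.21725
86 0.214814
87 0.212433
88 0.210105
89 0.207828
90 0.205601
91 0.203422
92 0.201289
93 0.199202
94 0.197158
95 0.195157
96 0.193196
97 0.191275
98 0.189393
99 0.187548
100 0.185739
101 0.184557
102 0.183394
103 0.18225
104 0.181123
105 0.180014
106 0.178923
107 0.177848
108 0.17679
109 0.175747
110 0.174721
111 0.173709
112 0.172712
113 0.17173
114 0.170762
115 0.169807
116 0.168867
117 0.167939
118 0.167025
119 0.166123
120 0.165233
121 0.164355
122 0.16349
123 0.162636
124 0.161793
125 0.160961
126 0.16014
127 0.15933
128 0.15853
129 0.157741
130 0.156961
131 0.156191
132 0.155431
133 0.15468
134 0.153938
135 0.153206
136 0.152482
137 0.151767
138 0.15106
139 0.150362
140 0.149672
141 0.14899
142 0.148316
143 0.14765
144 0.146991
145 0.14634
146 0.145696
147 0.145059
148 0.144429
149 0.143806
150 0.143191
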