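# material: Mg (element Z=12, A=24.305)
# nominal_z: 12
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 21.2846
11 16.097
12 12.4734
13 9.86503
14 7.93899
15 6.4855
16 5.38303
17 4.51874
18 3.83137
19 3.27768
20 2.82655
21 2.47885
22 2.18724
23 1.9407
24 1.73074
25 1.55073
26 1.39543
27 1.2607
28 1.1432
29 1.04021
30 0.949532
31 0.881667
32 0.820582
33 0.765418
34 0.715448
35 0.67005
36 0.628693
37 0.59092
38 0.556334
39 0.524594
40 0.495401
41 0.474006
42 0.454018
43 0.435314
44 0.417784
45 0.401331
46 0.385866
47 0.371311
48 0.357594
49 0.344652
50 0.332425
51 0.323478
52 0.314939
53 0.306781
54 0.298981
55 0.291518
56 0.28437
57 0.277519
58 0.270948
59 0.264642
60 0.258584
61 0.254466
62 0.25048
63 0.246618
64 0.242875
65 0.239246
66 0.235725
67 0.232308
68 0.228989
69 0.225766
70 0.222633
71 0.219588
72 0.216625
73 0.213743
74 0.210938
75 0.208206
76 0.205545
77 0.202952
78 0.200425
79 0.197961
80 0.195557
81 0.193956
82 0.192387
83 0.19085
84 0.189343
85 0.187865
86 0.186417
87 0.184996
88 0.183601
89 0.182233
90 0.180891
91 0.179572
92 0.178278
93 0.177007
94 0.175758
95 0.174531
96 0.173326
97 0.172141
98 0.170976
99 0.169831
100 0.168705
101 0.167914
102 0.167134
103 0.166366
104 0.165608
105 0.164861
106 0.164124
107 0.163398
108 0.162682
109 0.161975
110 0.161277
111 0.160589
112 0.15991
113 0.15924
114 0.158579
115 0.157926
116 0.157281
117 0.156645
118 0.156016
119 0.155395
120 0.154782
121 0.154177
122 0.153578
123 0.152987
124 0.152403
125 0.151826
126 0.151255
127 0.150692
128 0.150134
129 0.149583
130 0.149039
131 0.1485
132 0.147968
133 0.147441
134 0.14692
135 0.146405
136 0.145895
137 0.145391
138 0.144893
139 0.144399
140 0.143911
141 0.143428
142 0.14295
143 0.142477
144 0.142009
145 0.141545
146 0.141086
147 0.140632
148 0.140182
149 0.139737
150 0.139296
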