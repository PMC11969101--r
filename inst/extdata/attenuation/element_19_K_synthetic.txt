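# material: K (element Z=19, A=39.098)
# nominal_z: 19
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 80.3352
11 60.5165
12 46.7256
13 36.8325
14 29.5508
15 24.0718
16 19.8578
17 16.5737
18 13.9765
19 11.8954
20 10.2083
21 8.85314
22 7.7289
23 6.7883
24 5.99519
25 5.32167
26 4.74594
27 4.25084
28 3.82267
29 3.45046
30 3.12533
31 2.85494
32 2.61545
33 2.40251
34 2.21252
35 2.04242
36 1.88965
37 1.75204
38 1.62773
39 1.51513
40 1.41288
41 1.32717
42 1.24854
43 1.17625
44 1.10968
45 1.04824
46 0.991441
47 0.938846
48 0.890062
49 0.844742
50 0.802577
51 0.767438
52 0.734477
53 0.703519
54 0.674408
55 0.647004
56 0.621177
57 0.596812
58 0.573801
59 0.552049
60 0.531466
61 0.515424
62 0.500116
63 0.485496
64 0.471525
65 0.458162
66 0.445374
67 0.433127
68 0.421391
69 0.410137
70 0.39934
71 0.388973
72 0.379016
73 0.369445
74 0.360241
75 0.351386
76 0.342861
77 0.334651
78 0.326739
79 0.319112
80 0.311755
81 0.306432
82 0.301263
83 0.296243
84 0.291365
85 0.286624
86 0.282014
87 0.27753
88 0.273167
89 0.268921
90 0.264788
91 0.260762
92 0.256841
93 0.25302
94 0.249296
95 0.245666
96 0.242125
97 0.238671
98 0.235302
99 0.232013
100 0.228803
101 0.226713
102 0.224662
103 0.22265
104 0.220675
105 0.218736
106 0.216832
107 0.214962
108 0.213126
109 0.211322
110 0.20955
111 0.207808
112 0.206096
113 0.204414
114 0.20276
115 0.201133
116 0.199533
117 0.19796
118 0.196412
119 0.19489
120 0.193391
121 0.191917
122 0.190466
123 0.189037
124 0.187631
125 0.186246
126 0.184882
127 0.183539
128 0.182217
129 0.180913
130 0.17963
131 0.178365
132 0.177118
133 0.17589
134 0.174679
135 0.173485
136 0.172308
137 0.171148
138 0.170004
139 0.168876
140 0.167763
141 0.166665
142 0.165583
143 0.164514
144 0.163461
145 0.162421
146 0.161394
147 0.160382
148 0.159382
149 0.158395
150 0.157421
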