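# material: Be (element Z=4, A=9.012)
# nominal_z: 4
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 0.928603
11 0.765195
12 0.641258
13 0.545054
14 0.468901
15 0.407599
16 0.369865
17 0.337608
18 0.309775
19 0.285563
20 0.264345
21 0.252734
22 0.242139
23 0.23243
24 0.2235
25 0.215256
26 0.207623
27 0.200533
28 0.19393
29 0.187766
30 0.181996
31 0.179559
32 0.17723
33 0.175002
34 0.172867
35 0.170819
36 0.168852
37 0.166961
38 0.16514
39 0.163386
40 0.161694
41 0.16072
42 0.159776
43 0.158859
44 0.157969
45 0.157103
46 0.156261
47 0.155441
48 0.154643
49 0.153865
50 0.153107
51 0.152494
52 0.151896
53 0.151311
54 0.150739
55 0.150181
56 0.149634
57 0.149098
58 0.148574
59 0.148061
60 0.147558
61 0.147067
62 0.146585
63 0.146113
64 0.145649
65 0.145194
66 0.144748
67 0.144309
68 0.143879
69 0.143455
70 0.14304
71 0.142631
72 0.142229
73 0.141834
74 0.141445
75 0.141062
76 0.140686
77 0.140315
78 0.13995
79 0.139591
80 0.139237
81 0.138849
82 0.138467
83 0.13809
84 0.137719
85 0.137353
86 0.136992
87 0.136637
88 0.136286
89 0.13594
90 0.135599
91 0.135263
92 0.134931
93 0.134604
94 0.13428
95 0.133961
96 0.133646
97 0.133335
98 0.133028
99 0.132725
100 0.132426
101 0.132079
102 0.131736
103 0.131397
104 0.131063
105 0.130733
106 0.130406
107 0.130084
108 0.129765
109 0.12945
110 0.129139
111 0.128831
112 0.128527
113 0.128226
114 0.127928
115 0.127634
116 0.127343
117 0.127055
118 0.12677
119 0.126488
120 0.126209
121 0.125933
122 0.12566
123 0.12539
124 0.125123
125 0.124858
126 0.124596
127 0.124336
128 0.12408
129 0.123825
130 0.123573
131 0.123324
132 0.123077
133 0.122832
134 0.12259
135 0.12235
136 0.122112
137 0.121876
138 0.121642
139 0.121411
140 0.121182
141 0.120955
142 0.120729
143 0.120506
144 0.120285
145 0.120066
146 0.119848
147 0.119633
148 0.119419
149 0.119207
150 0.118997
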