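# material: F (element Z=9, A=18.998)
# nominal_z: 9
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 8.87472
11 6.75733
12 5.2687
13 4.1907
14 3.39032
15 2.78323
16 2.3332
17 1.97698
18 1.69108
19 1.4588
20 1.268
21 1.12955
22 1.01164
23 0.910488
24 0.823136
25 0.747235
26 0.680911
27 0.622656
28 0.571239
29 0.525656
30 0.485076
31 0.458417
32 0.434002
33 0.411579
34 0.390934
35 0.371879
36 0.35425
37 0.337907
38 0.322724
39 0.308592
40 0.295413
41 0.286859
42 0.27875
43 0.271054
44 0.263739
45 0.25678
46 0.250151
47 0.24383
48 0.237798
49 0.232034
50 0.226523
51 0.222773
52 0.219157
53 0.215667
54 0.212296
55 0.209039
56 0.205888
57 0.20284
58 0.199889
59 0.197029
60 0.194258
61 0.192407
62 0.190604
63 0.188846
64 0.187131
65 0.185459
66 0.183826
67 0.182232
68 0.180675
69 0.179154
70 0.177667
71 0.176214
72 0.174792
73 0.173401
74 0.17204
75 0.170708
76 0.169404
77 0.168126
78 0.166874
79 0.165647
80 0.164445
81 0.163586
82 0.162741
83 0.161911
84 0.161095
85 0.160293
86 0.159504
87 0.158728
88 0.157964
89 0.157213
90 0.156474
91 0.155746
92 0.15503
93 0.154324
94 0.15363
95 0.152945
96 0.152271
97 0.151607
98 0.150953
99 0.150307
100 0.149671
101 0.149147
102 0.148629
103 0.148117
104 0.147613
105 0.147115
106 0.146623
107 0.146138
108 0.145659
109 0.145185
110 0.144718
111 0.144256
112 0.1438
113 0.143349
114 0.142904
115 0.142464
116 0.142029
117 0.141599
118 0.141174
119 0.140754
120 0.140339
121 0.139928
122 0.139522
123 0.139121
124 0.138723
125 0.138331
126 0.137942
127 0.137557
128 0.137177
129 0.1368
130 0.136428
131 0.136059
132 0.135694
133 0.135333
134 0.134976
135 0.134622
136 0.134271
137 0.133924
138 0.133581
139 0.133241
140 0.132904
141 0.13257
142 0.13224
143 0.131913
144 0.131588
145 0.131267
146 0.130949
147 0.130634
148 0.130321
149 0.130012
150 0.129705
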