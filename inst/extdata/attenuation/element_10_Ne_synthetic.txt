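# material: Ne (element Z=10, A=20.180)
# nominal_z: 10
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 12.5815
11 9.54992
12 7.42492
13 5.89032
14 4.7538
15 3.89375
16 3.24956
17 2.74185
18 2.33604
19 2.00761
20 1.73882
21 1.53859
22 1.36919
23 1.22477
24 1.1008
25 0.993693
26 0.900618
27 0.819298
28 0.74789
29 0.684894
30 0.629078
31 0.590379
32 0.555178
33 0.523065
34 0.493687
35 0.466741
36 0.441963
37 0.419127
38 0.398034
39 0.378509
40 0.360401
41 0.348104
42 0.336508
43 0.325558
44 0.315203
45 0.3054
46 0.296107
47 0.287288
48 0.278909
49 0.27094
50 0.263352
51 0.258076
52 0.253005
53 0.248127
54 0.243432
55 0.23891
56 0.23455
57 0.230346
58 0.226288
59 0.222369
60 0.218582
61 0.216062
62 0.213612
63 0.211228
64 0.208907
65 0.206648
66 0.204446
67 0.202301
68 0.20021
69 0.19817
70 0.19618
71 0.194238
72 0.192341
73 0.190489
74 0.18868
75 0.186912
76 0.185183
77 0.183493
78 0.18184
79 0.180222
80 0.178639
81 0.177549
82 0.17648
83 0.175429
84 0.174397
85 0.173384
86 0.172388
87 0.171409
88 0.170447
89 0.169501
90 0.168571
91 0.167656
92 0.166756
93 0.16587
94 0.164999
95 0.164141
96 0.163297
97 0.162465
98 0.161647
99 0.16084
100 0.160046
101 0.159431
102 0.158824
103 0.158226
104 0.157635
105 0.157053
106 0.156477
107 0.15591
108 0.15535
109 0.154797
110 0.15425
111 0.153711
112 0.153179
113 0.152653
114 0.152133
115 0.15162
116 0.151112
117 0.150611
118 0.150116
119 0.149627
120 0.149143
121 0.148665
122 0.148192
123 0.147724
124 0.147262
125 0.146805
126 0.146353
127 0.145906
128 0.145464
129 0.145026
130 0.144594
131 0.144166
132 0.143742
133 0.143323
134 0.142908
135 0.142497
136 0.142091
137 0.141689
138 0.14129
139 0.140896
140 0.140506
141 0.140119
142 0.139737
143 0.139358
144 0.138982
145 0.138611
146 0.138242
147 0.137878
148 0.137516
149 0.137158
150 0.136804
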