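# material: Ar (element Z=18, A=39.948)
# nominal_z: 18
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 63.567
11 47.8966
12 36.9897
13 29.1639
14 23.4026
15 19.0669
16 15.735
17 13.1375
18 11.0825
19 9.43538
20 8.09963
21 7.02956
22 6.14121
23 5.39745
24 4.7699
25 4.23665
26 3.78055
27 3.38808
28 3.04849
29 2.75312
30 2.49498
31 2.28187
32 2.09288
33 1.92467
34 1.7744
35 1.63973
36 1.51865
37 1.40948
38 1.31075
39 1.22124
40 1.13989
41 1.07242
42 1.01042
43 0.953346
44 0.900697
45 0.852043
46 0.807002
47 0.765235
48 0.726442
49 0.690356
50 0.656738
51 0.629069
52 0.603069
53 0.578609
54 0.55557
55 0.533847
56 0.513343
57 0.493968
58 0.475642
59 0.458292
60 0.441852
61 0.429258
62 0.41722
63 0.405705
64 0.39468
65 0.38412
66 0.373997
67 0.364287
68 0.354967
69 0.346017
70 0.337416
71 0.329147
72 0.321192
73 0.313535
74 0.30616
75 0.299055
76 0.292206
77 0.2856
78 0.279225
79 0.273072
80 0.267129
81 0.262904
82 0.258796
83 0.254802
84 0.250915
85 0.247133
86 0.243451
87 0.239866
88 0.236374
89 0.23297
90 0.229654
91 0.22642
92 0.223266
93 0.22019
94 0.217188
95 0.214259
96 0.211399
97 0.208606
98 0.205878
99 0.203213
100 0.200609
101 0.198923
102 0.197267
103 0.195641
104 0.194044
105 0.192476
106 0.190934
107 0.18942
108 0.187931
109 0.186467
110 0.185028
111 0.183613
112 0.182222
113 0.180853
114 0.179507
115 0.178182
116 0.176878
117 0.175595
118 0.174331
119 0.173088
120 0.171864
121 0.170658
122 0.169471
123 0.168301
124 0.167149
125 0.166014
126 0.164896
127 0.163794
128 0.162708
129 0.161637
130 0.160582
131 0.159542
132 0.158516
133 0.157504
134 0.156507
135 0.155523
136 0.154552
137 0.153595
138 0.15265
139 0.151718
140 0.150798
141 0.149891
142 0.148995
143 0.148111
144 0.147238
145 0.146376
146 0.145525
147 0.144685
148 0.143855
149 0.143036
150 0.142226
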