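# material: O (element Z=8, A=15.999)
# nominal_z: 8
# source: synthetic: Klein-Nishina + fitted Z^2.94 photoelectric model, scaled so Z=13 matches the Al reference (see data-raw/build_attenuation_tables.R)
# grid: 1 keV, 10-150 keV, densified from 10 anchor energies by log-log interpolation
# columns: energy_keV mu_over_rho_cm2_g
10 6.68458
11 5.11367
12 4.00425
13 3.19754
14 2.5963
15 2.13864
16 1.8045
17 1.53833
18 1.32345
19 1.14788
20 1.0029
21 0.901358
22 0.814131
23 0.73868
24 0.673002
25 0.615499
26 0.564885
27 0.520115
28 0.480333
29 0.444835
30 0.413034
31 0.3935
32 0.375467
33 0.358778
34 0.343297
35 0.328903
36 0.315494
37 0.302977
38 0.291271
39 0.280303
40 0.270011
41 0.263643
42 0.257572
43 0.251779
44 0.246246
45 0.240954
46 0.235888
47 0.231035
48 0.226381
49 0.221913
50 0.217621
51 0.214745
52 0.211961
53 0.209266
54 0.206654
55 0.204122
56 0.201665
57 0.199281
58 0.196966
59 0.194717
60 0.19253
61 0.19104
62 0.189586
63 0.188166
64 0.186779
65 0.185423
66 0.184097
67 0.182801
68 0.181533
69 0.180292
70 0.179077
71 0.177887
72 0.176722
73 0.17558
74 0.174461
75 0.173364
76 0.172288
77 0.171233
78 0.170198
79 0.169182
80 0.168185
81 0.167431
82 0.16669
83 0.165961
84 0.165243
85 0.164538
86 0.163843
87 0.163159
88 0.162486
89 0.161824
90 0.161171
91 0.160528
92 0.159895
93 0.159271
94 0.158656
95 0.15805
96 0.157453
97 0.156864
98 0.156283
99 0.15571
100 0.155145
101 0.154644
102 0.154149
103 0.153661
104 0.15318
105 0.152704
106 0.152234
107 0.15177
108 0.151312
109 0.150859
110 0.150412
111 0.14997
112 0.149534
113 0.149102
114 0.148676
115 0.148254
116 0.147838
117 0.147426
118 0.147019
119 0.146616
120 0.146218
121 0.145824
122 0.145434
123 0.145049
124 0.144667
125 0.14429
126 0.143917
127 0.143548
128 0.143182
129 0.14282
130 0.142462
131 0.142108
132 0.141757
133 0.14141
134 0.141066
135 0.140725
136 0.140388
137 0.140054
138 0.139723
139 0.139396
140 0.139072
141 0.13875
142 0.138432
143 0.138116
144 0.137804
145 0.137494
146 0.137187
147 0.136883
148 0.136582
149 0.136283
150 0.135987
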