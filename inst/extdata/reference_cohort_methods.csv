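subject,method,accuracy,std
1,1,67.74,0.072
2,1,86.27,0.670
3,1,65.89,0.030
4,1,70.21,0.082
5,1,72.31,0.012
6,1,57.55,0.130
7,1,71.23,0.230
8,1,64.33,0.120
9,1,91.22,0.020
10,1,73.30,0.060
11,1,64.32,0.040
12,1,59.11,0.210
1,2,71.50,0.061
2,2,86.22,0.055
3,2,66.48,0.062
4,2,72.23,0.094
5,2,68.23,0.073
6,2,62.58,0.087
7,2,74.33,0.097
8,2,67.36,0.150
9,2,91.24,0.030
10,2,75.52,0.055
11,2,68.22,0.057
12,2,52.50,0.077
1,3-1,63.21,0.073
2,3-1,83.22,0.140
3,3-1,54.39,0.150
4,3-1,58.68,0.140
5,3-1,64.00,0.150
6,3-1,47.17,0.240
7,3-1,63.71,0.130
8,3-1,65.82,0.040
9,3-1,74.51,0.180
10,3-1,56.88,0.120
11,3-1,66.72,0.080
12,3-1,54.71,0.130
1,3-2,65.36,0.051
2,3-2,84.73,0.062
3,3-2,56.51,0.120
4,3-2,63.22,0.230
5,3-2,65.83,0.068
6,3-2,43.47,0.252
7,3-2,66.83,0.234
8,3-2,71.36,0.079
9,3-2,72.37,0.237
10,3-2,60.58,0.103
11,3-2,68.19,0.093
12,3-2,57.81,0.170
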