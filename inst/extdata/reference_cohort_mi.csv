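subject,condition,accuracy,std
1,low,85.01,0.072
2,low,91.02,0.030
3,low,72.99,0.082
4,low,70.04,0.012
5,low,87.44,0.030
6,low,68.18,0.230
7,low,87.12,0.120
8,low,57.73,0.150
9,low,97.55,0.070
10,low,78.72,0.090
11,low,74.33,0.030
12,low,53.20,0.220
1,mid,70.00,0.065
2,mid,95.03,0.040
3,mid,67.67,0.130
4,mid,74.25,0.060
5,mid,78.65,0.030
6,mid,60.33,0.220
7,mid,76.28,0.140
8,mid,60.09,0.092
9,mid,91.00,0.210
10,mid,74.17,0.174
11,mid,67.43,0.090
12,mid,60.10,0.130
1,high,55.21,0.150
2,high,67.69,0.230
3,high,59.23,0.170
4,high,55.27,0.220
5,high,53.25,0.310
6,high,51.24,0.110
7,high,64.65,0.080
8,high,64.40,0.140
9,high,73.20,0.270
10,high,83.36,0.110
11,high,46.71,0.160
12,high,64.69,0.220
1,all,63.17,0.220
2,all,83.25,0.330
3,all,54.41,0.120
4,all,58.75,0.130
5,all,64.03,0.090
6,all,47.17,0.140
7,all,63.70,0.173
8,all,65.81,0.182
9,all,74.49,0.224
10,all,56.93,0.120
11,all,66.67,0.230
12,all,54.73,0.320
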