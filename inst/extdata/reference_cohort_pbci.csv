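subject,pbci_accuracy,pbci_std
1,84.2,0.045
2,87.5,0.152
3,81.3,0.061
4,83.6,0.158
5,86.7,0.049
6,82.9,0.072
7,88.1,0.244
8,84.5,0.066
9,90.2,0.037
10,83.7,0.159
11,86.1,0.051
12,83.3,0.063
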