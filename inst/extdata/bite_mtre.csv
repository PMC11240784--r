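case,pre_mean,pre_sd,post_mean,post_sd
1,5.88,2.31,1.84,1.23
2,6.06,1.61,1.50,0.54
3,8.91,2.02,1.51,0.26
4,3.87,1.19,1.76,1.09
5,2.57,1.61,1.94,0.26
6,2.24,1.05,1.14,0.31
7,3.02,1.58,1.45,0.16
8,3.75,1.97,1.00,0.49
9,5.05,1.33,0.96,0.42
10,2.99,1.34,0.96,0.25
11,1.51,0.73,1.30,0.52
12,3.68,1.85,1.13,0.23
13,5.13,2.73,1.37,0.57
14,3.78,1.23,1.08,0.45
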