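case,pre,post_adversarial,post_full
1,1.86,0.8184,0.7377
2,5.75,1.7625,1.1266
3,9.63,1.5289,0.9664
4,2.98,0.8520,0.5183
5,12.20,1.5311,1.4715
6,3.34,0.4644,0.2992
7,1.88,0.7826,0.5380
8,2.65,0.7109,0.6584
12,19.76,1.2702,0.8793
13,4.71,0.59665,0.5946
14,3.03,0.5196,0.4340
15,3.37,1.0292,0.8440
16,3.41,1.1579,1.1256
17,6.41,0.6660,0.8418
18,3.66,1.2277,0.7604
19,3.16,1.2741,1.0548
21,4.46,1.5884,0.7350
23,7.05,0.7250,0.4869
24,1.13,0.4679,0.3606
25,10.10,1.0692,0.8131
26,2.93,0.4731,0.3179
27,5.86,1.0950,1.0493
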