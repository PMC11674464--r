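children,cdf
0,0.15
1,0.28
2,0.53
3,0.74
4,0.87
5,0.94
6,0.975
7,0.99
8,1
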