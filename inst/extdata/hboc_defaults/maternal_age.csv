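age,prob
16,0.01199983
17,0.01670104
18,0.02248822
19,0.0292961
20,0.03692392
21,0.04502449
22,0.05311694
23,0.06062621
24,0.06694697
25,0.07152282
26,0.07392673999999999
27,0.07392672
28,0.07152282
29,0.06694697
30,0.06062621
31,0.05311694
32,0.04502449
33,0.03692392
34,0.0292961
35,0.02248822
36,0.01670104
37,0.01199983
38,0.00834161
39,0.00561006
40,0.0036503
41,0.00229791
42,0.00139952
43,8.2465e-4
44,4.7012e-4
45,2.5929e-4
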