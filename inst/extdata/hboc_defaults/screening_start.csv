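age,prob
40,0.03
41,0.03
42,0.03
43,0.03
44,0.03
45,0.02
46,0.02
47,0.02
48,0.02
49,0.02
50,0.3
51,0.05
52,0.05
53,0.05
54,0.05
55,0.03
56,0.03
57,0.03
58,0.03
59,0.03
60,0.02
61,0.02
62,0.02
63,0.02
64,0.02
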