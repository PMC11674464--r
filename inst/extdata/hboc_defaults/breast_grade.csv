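subtype,grade,prob
TN,1,0.03
TN,2,0.17
TN,3,0.8
HER2,1,0.1
HER2,2,0.4
HER2,3,0.5
HRplus,1,0.3
HRplus,2,0.5
HRplus,3,0.2
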