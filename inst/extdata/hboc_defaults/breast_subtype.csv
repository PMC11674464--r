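gene,subtype,prob
none,TN,0.11
none,HER2,0.13
none,HRplus,0.76
BRCA1,TN,0.61
BRCA1,HER2,0.05
BRCA1,HRplus,0.34
BRCA2,TN,0.16
BRCA2,HER2,0.05
BRCA2,HRplus,0.79
PALB2,TN,0.3
PALB2,HER2,0.05
PALB2,HRplus,0.65
CHEK2_1100delC,TN,0.05
CHEK2_1100delC,HER2,0.1
CHEK2_1100delC,HRplus,0.85
ATM,TN,0.05
ATM,HER2,0.1
ATM,HRplus,0.85
RAD51C,TN,0.3
RAD51C,HER2,0.1
RAD51C,HRplus,0.6
RAD51D,TN,0.3
RAD51D,HER2,0.1
RAD51D,HRplus,0.6
BRIP1,TN,0.11
BRIP1,HER2,0.13
BRIP1,HRplus,0.76
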