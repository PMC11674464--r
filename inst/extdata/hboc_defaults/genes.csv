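gene,prevalence
BRCA1,0.002
BRCA2,0.003
PALB2,0.002
CHEK2_1100delC,0.0026
ATM,0.005
RAD51C,8e-4
RAD51D,5e-4
BRIP1,0.001
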