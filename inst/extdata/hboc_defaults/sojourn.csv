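gene,meanlog,sdlog
none,1.098612,0.55
BRCA1,0.587787,0.5
BRCA2,0.916291,0.5
PALB2,0.916291,0.5
CHEK2_1100delC,1.098612,0.55
ATM,1.098612,0.55
RAD51C,1.098612,0.55
RAD51D,1.098612,0.55
BRIP1,1.098612,0.55
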