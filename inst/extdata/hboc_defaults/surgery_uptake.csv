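surgery,gene,age_lo,age_hi,annual_prob
BRRM,BRCA1,18,39,0.045
BRRM,BRCA1,40,49,0.03
BRRM,BRCA1,50,59,0.015
BRRM,BRCA1,60,100,0.005
BRRM,BRCA2,18,39,0.045
BRRM,BRCA2,40,49,0.03
BRRM,BRCA2,50,59,0.015
BRRM,BRCA2,60,100,0.005
BRRM,PALB2,18,39,0.045
BRRM,PALB2,40,49,0.03
BRRM,PALB2,50,59,0.015
BRRM,PALB2,60,100,0.005
BRRM,ATM,18,39,0.0225
BRRM,ATM,40,49,0.015
BRRM,ATM,50,59,0.0075
BRRM,ATM,60,100,0.0025
BRRM,CHEK2_1100delC,18,39,0.0225
BRRM,CHEK2_1100delC,40,49,0.015
BRRM,CHEK2_1100delC,50,59,0.0075
BRRM,CHEK2_1100delC,60,100,0.0025
RRSO,BRCA1,35,44,0.07
RRSO,BRCA1,45,54,0.11
RRSO,BRCA1,55,100,0.05
RRSO,BRCA2,40,44,0.06
RRSO,BRCA2,45,54,0.1
RRSO,BRCA2,55,100,0.05
RRSO,PALB2,50,54,0.1
RRSO,PALB2,55,100,0.05
RRSO,RAD51C,45,54,0.1
RRSO,RAD51C,55,100,0.05
RRSO,RAD51D,45,54,0.1
RRSO,RAD51D,55,100,0.05
RRSO,BRIP1,60,100,0.05
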