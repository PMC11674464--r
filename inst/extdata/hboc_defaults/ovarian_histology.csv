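age_band,histology,prob
<50,serous,0.35
<50,endometrioid,0.25
<50,clear_cell,0.15
<50,mucinous,0.15
<50,other,0.1
50-69,serous,0.5
50-69,endometrioid,0.18
50-69,clear_cell,0.1
50-69,mucinous,0.1
50-69,other,0.12
70+,serous,0.6
70+,endometrioid,0.1
70+,clear_cell,0.05
70+,mucinous,0.08
70+,other,0.17
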