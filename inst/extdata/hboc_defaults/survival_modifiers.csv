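type,level,multiplier
histology,serous,1.1
histology,clear_cell,1.2
histology,endometrioid,0.7
histology,mucinous,0.8
histology,other,1
age,<50,0.85
age,50-69,1
age,70+,1.3
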