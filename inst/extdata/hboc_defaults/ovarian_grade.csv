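histology,grade,prob
serous,1,0.1
serous,2,0.2
serous,3,0.7
endometrioid,1,0.3
endometrioid,2,0.4
endometrioid,3,0.3
clear_cell,1,0.05
clear_cell,2,0.35
clear_cell,3,0.6
mucinous,1,0.55
mucinous,2,0.3
mucinous,3,0.15
other,1,0.2
other,2,0.3
other,3,0.5
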