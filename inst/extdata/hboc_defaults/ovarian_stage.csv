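histology,grade,stage,prob
serous,1,local,0.35
serous,1,regional,0.3
serous,1,distant,0.35
serous,2,local,0.23
serous,2,regional,0.3
serous,2,distant,0.47
serous,3,local,0.11
serous,3,regional,0.3
serous,3,distant,0.59
endometrioid,1,local,0.55
endometrioid,1,regional,0.3
endometrioid,1,distant,0.15
endometrioid,2,local,0.43
endometrioid,2,regional,0.3
endometrioid,2,distant,0.27
endometrioid,3,local,0.31
endometrioid,3,regional,0.3
endometrioid,3,distant,0.39
clear_cell,1,local,0.55
clear_cell,1,regional,0.3
clear_cell,1,distant,0.15
clear_cell,2,local,0.43
clear_cell,2,regional,0.3
clear_cell,2,distant,0.27
clear_cell,3,local,0.31
clear_cell,3,regional,0.3
clear_cell,3,distant,0.39
mucinous,1,local,0.55
mucinous,1,regional,0.3
mucinous,1,distant,0.15
mucinous,2,local,0.43
mucinous,2,regional,0.3
mucinous,2,distant,0.27
mucinous,3,local,0.31
mucinous,3,regional,0.3
mucinous,3,distant,0.39
other,1,local,0.55
other,1,regional,0.3
other,1,distant,0.15
other,2,local,0.43
other,2,regional,0.3
other,2,distant,0.27
other,3,local,0.31
other,3,regional,0.3
other,3,distant,0.39
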