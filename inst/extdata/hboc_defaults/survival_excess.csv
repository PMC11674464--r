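organ,stage,yrs_lo,yrs_hi,rate
breast,local,0,4,0.005
breast,local,5,9,0.003
breast,local,10,100,0.001
breast,regional,0,4,0.03
breast,regional,5,9,0.018
breast,regional,10,100,0.007
breast,distant,0,4,0.25
breast,distant,5,9,0.15
breast,distant,10,100,0.07
ovary,local,0,4,0.02
ovary,local,5,9,0.012
ovary,local,10,100,0.005
ovary,regional,0,4,0.09
ovary,regional,5,9,0.05
ovary,regional,10,100,0.02
ovary,distant,0,4,0.3
ovary,distant,5,9,0.18
ovary,distant,10,100,0.08
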