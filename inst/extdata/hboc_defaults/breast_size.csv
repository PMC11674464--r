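mode,size_class,prob
screen,<=10,0.45
screen,11-20,0.4
screen,21-50,0.13
screen,>50,0.02
symptomatic,<=10,0.15
symptomatic,11-20,0.4
symptomatic,21-50,0.38
symptomatic,>50,0.07
baseline,<=10,0.15
baseline,11-20,0.4
baseline,21-50,0.38
baseline,>50,0.07
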