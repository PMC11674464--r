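context,years,prob
population,0,0.7
population,1,0.2
population,2,0.07
population,3,0.03
highrisk_start,0,0.5
highrisk_start,1,0.25
highrisk_start,2,0.15
highrisk_start,3,0.1
highrisk_interval,0,0.75
highrisk_interval,1,0.15
highrisk_interval,2,0.07
highrisk_interval,3,0.03
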