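modality,age_lo,age_hi,sens,spec
mammography,0,39,0.6,0.94
mammography,40,49,0.75,0.95
mammography,50,59,0.85,0.96
mammography,60,100,0.88,0.97
mri,0,100,0.9,0.88
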