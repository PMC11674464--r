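cancer,term,or
breast,constant,3.23
breast,age_40_49,0.38
breast,age_50_69,0.22
breast,age_70p,0.1
breast,survival_lt12m,0.35
breast,high_grade,2.37
breast,non_tn,0.5
breast,her2,0.22
ovary,constant,3.09
ovary,age_60_74,0.2
ovary,age_75p,0.08
ovary,survival_lt12m,0.04
ovary,high_grade,1.06
ovary,prior_breast,17.75
ovary,mucinous,0.08
ovary,other_hist,0.2
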