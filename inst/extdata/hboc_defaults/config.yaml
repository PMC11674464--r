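tables:
  genes: genes.csv
  baseline_incidence: baseline_incidence.csv
  penetrance: penetrance.csv
  polygenic: polygenic.csv
  referral: referral.csv
  testing_uptake: testing_uptake.csv
  predictive_uptake: predictive_uptake.csv
  parity_completed: parity_completed.csv
  parity_age: parity_age.csv
  maternal_age: maternal_age.csv
  lifetable: lifetable.csv
  screening_performance: screening_performance.csv
  screening_start: screening_start.csv
  screening_delay: screening_delay.csv
  surgery_uptake: surgery_uptake.csv
  survival_excess: survival_excess.csv
  survival_modifiers: survival_modifiers.csv
  breast_subtype: breast_subtype.csv
  breast_grade: breast_grade.csv
  breast_size: breast_size.csv
  breast_nodes: breast_nodes.csv
  breast_met: breast_met.csv
  ovarian_histology: ovarian_histology.csv
  ovarian_grade: ovarian_grade.csv
  ovarian_stage: ovarian_stage.csv
  sojourn: sojourn.csv
constants:
  male_rate_ratio: 0.422
  max_children: 8
  never_screen: 0.3
  polygenic_corr: 0.0
  brrm_multiplier: 0.1
  rrso_ovary_multiplier: 0.05
  rrso_breast_multiplier: 1.0
  crrm_uptake_carrier: 0.35
  crrm_uptake_noncarrier: 0.05
  nodes_screen_multiplier: 0.7
  pop_screen_interval: 2
  hr_screen_interval: 1
  pop_screen_stop: 74
  pop_start_lo: 40
  pop_start_hi: 64
  hr_mammo_lo: 25
  hr_mammo_hi: 64
  hr_mri_lo: 25
  hr_mri_hi: 59
  mod_mammo_lo: 35
  mod_mammo_hi: 59
  moderate_start_delay: 10
  spouse_gap_mean: 2.0
  spouse_gap_sd: 3.0
  paternal_shift: 2
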