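# Default parameter bundle — provenance

Every table here is loadable and overridable through `load_parameters()`.
Two classes of values are shipped:

## Published, encoded verbatim

- `referral.csv` — referral odds model for newly diagnosed breast/ovarian
  cancer (constant odds plus odds-ratio terms for age band, survival under
  12 months, grade, subtype/histology, prior breast cancer), from an
  Australian familial-cancer-service analysis.
- `testing_uptake.csv` — diagnostic testing uptake 0.96 (breast) and 0.95
  (ovarian).
- `predictive_uptake.csv` — annual cascade-testing probabilities by degree
  of relation, age band, and time since the family variant was identified;
  a rate ratio of 0.422 applies to male relatives
  (`constants: male_rate_ratio`); under-18s are zero.

## Literature-anchored stand-ins (SYNTHETIC defaults)

The remaining tables are calibrated stand-ins constructed for this package,
not published datasets. Anchors:

- `genes.csv` — carrier frequencies of the order reported for
  population-based Australian screening cohorts (BRCA2 > BRCA1, ATM the most
  common moderate-risk allele; total carrier frequency ~1.7%).
- `baseline_incidence.csv` — non-carrier hazards calibrated to an
  Australian-style female lifetime breast-cancer risk of roughly 1 in 7 to
  age 85 (~14%) and ovarian risk ~1.1%.
- `penetrance.csv` — carrier hazards from cumulative-risk knots in line with
  large international cohort estimates (e.g. BRCA1 breast ~72% and ovary
  ~44% to age 80; BRCA2 69%/17%; PALB2 53%/5%; moderate-risk genes as
  relative risks ~1.6-2.1 on the baseline).
- `polygenic.csv` — hazard ratio per SD of polygenic score: 1.6 breast,
  1.3 ovary.
- `parity_completed.csv`, `maternal_age.csv` — completed parity (mean ~2.5,
  15% childless, capped at 8) and maternal age at birth (truncated normal,
  mean 27, sd 5.5), jointly calibrated so that families of probands aged
  50-54 average ~22 first/second-degree members including deceased.
  `parity_age.csv` is derived from these two (births as independent
  maternal-age draws).
- `lifetable.csv` — Gompertz-Makeham stand-ins; the female table plays the
  role of a cause-deleted (net of breast/ovarian cancer) lifetable.
- `screening_*.csv` — mammography sensitivity/specificity by age band, MRI
  performance, a participation-start distribution giving 30% never-screeners
  (`constants: never_screen`), and delay distributions for inter-screen
  intervals.
- `surgery_uptake.csv` — annual uptake of risk-reducing mastectomy and
  salpingo-oophorectomy by gene and age; PALB2 at the BRCA2 rate, ATM/CHEK2
  at half the BRCA2 rate, RRSO eligibility from 45 (RAD51C/D), 50 (PALB2),
  60 (BRIP1). Risk-reduction multipliers in `constants`
  (BRRM 0.10, RRSO ovary 0.05, RRSO breast effect off by default).
- `survival_excess.csv`, `survival_modifiers.csv` — annual excess mortality
  by organ, stage and years since diagnosis, with ovarian histology and age
  multipliers; approximate modern registry relative survival (e.g. breast
  5-year survival ~97/86/29% local/regional/distant).
- `breast_*.csv`, `ovarian_*.csv` — conditional tumour-characteristic
  models: subtype by genotype (triple-negative enrichment in BRCA1),
  grade by subtype, size/nodes/metastasis by detection mode, ovarian
  histology by age (serous share increasing at 70+), grade by histology,
  stage by histology and grade (advanced stage more likely for high grade
  and serous).
- `sojourn.csv` — lognormal preclinical sojourn time; shorter for BRCA1
  (median 1.8y) than non-carriers (median 3y).
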