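---
title: "A family-structured microsimulation of HBOC genetic testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A family-structured microsimulation of HBOC genetic testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbocsim)
```

## What the model is

`hbocsim` simulates hereditary breast and ovarian cancer (HBOC) and its
clinical management inside proband-centred family units, in discrete yearly
cycles. It exists to study *cascade* genetic testing: once a pathogenic or
likely pathogenic (P/LP) variant is found in a cancer-affected woman, her
relatives become eligible for targeted predictive testing, and positive
relatives gain access to intensified surveillance and risk-reducing surgery.
Whether expanding the initial (diagnostic) testing criteria helps therefore
depends on family structure, on how many relatives actually test, and on
when — questions that per-individual models answer only through
simplifying assumptions. Here relatives are simulated explicitly.

## Population generation

Each family is built around a cancer-free female proband entering at a
configurable age (20–59). Two parents and four grandparents always exist;
siblings, aunts/uncles (piblings), children, nieces/nephews (niblings) and
grandchildren are generated from a completed-parity distribution (mean ~2.5,
15% childless, capped at 8 children) combined with a maternal-age-at-birth
schedule (truncated normal, mean 26.5, sd 5.5; fathers shifted +2 years).
Children whose birth date lies in the simulated future are created as
*unborn* and activate during a dynamic-population run, provided their mother
is alive in the birth year. Married-in co-parents are generated only to
supply the second allele and are excluded from family-size metrics. With
these defaults a family of a proband aged 50–54 averages ~22 members
including the deceased, which is what the generator was calibrated to.

Monogenic genotypes use eight genes (BRCA1, BRCA2, PALB2, CHEK2 restricted
to 1100delC, ATM, RAD51C, RAD51D, BRIP1) with at most one variant per
person, sampled in founders at population carrier frequencies and
transmitted with probability 1/2 from a heterozygous parent; there are no
de novo events. The polygenic component is an infinitesimal-model pair of
scores (breast, ovary): founders are standard normal, children receive the
midparent mean plus segregation noise of variance 1/2, which preserves unit
marginal variance in every generation (a property the test suite checks).
The two scores are independent by default; their correlation is exposed as
`constants$polygenic_corr`.

Every relative's pre-entry history is then *replayed* from birth to entry
age under the same natural-history model (without screening — pre-entry
tumours carry detection mode `"baseline"`), which yields prevalent cancers,
vital status, and cause/age of death consistent with the lifetables.
Probands are cancer-free and alive at entry by definition and are not
replayed.

## Natural history

The annual onset probability is `1 − exp(−h)` with

`h = h(gene, organ, age) × HR^z / E[HR^z]`,

where the genotype-specific hazard curves are piecewise-constant on integer
ages 0–100 (cumulative-risk inputs are converted by differencing and
`−log(1−·)`), and the polygenic multiplier is normalised by
`E[HR^z] = exp((ln HR)²/2)` so that the population-average multiplier is
exactly 1 — simulated non-carrier incidence then recovers the input
incidence tables, which is the calibration that matters. A consequence
worth knowing: a woman at the polygenic median (z = 0) sits slightly
*below* the raw baseline curve (by the factor `1/E[HR^z]` ≈ 0.89 for
HR = 1.6), because the lognormal multiplier's mean exceeds its median.

Breast cancer begins as preclinical, screen-detectable disease; a lognormal
sojourn time (median 3 years for non-carriers, 1.8 for BRCA1) ends in
symptomatic diagnosis unless a screen detects the tumour or surgery removes
it first. A contralateral second course can follow a first diagnosis unless
contralateral or bilateral mastectomy intervenes. Ovarian cancer has no
preclinical phase; carriers diagnosed after 25 are high-grade serous, and
otherwise histology, grade and stage are drawn conditionally (advanced
stage more likely for high grade and serous histology). Survival applies
annual excess-mortality rates by organ × stage × years-since-diagnosis
bands with ovarian-histology and age multipliers, competing with a
sex-specific, cause-deleted lifetable; everyone exits at age 100.

Competing events within a cycle are resolved by sampling event times
uniformly within the year and taking the earliest, which removes
process-ordering bias at yearly resolution.

## Clinical pathways

**Referral and diagnostic testing.** Referral can only happen in a
diagnosis year (re-referral at each new primary). The probability is
`odds/(1+odds)` from the constant-times-odds-ratio model (breast constant
3.23; ovarian 3.09; terms for age band, grade, subtype/histology, survival
under 12 months — evaluated by peeking at the next cycle's own death draws,
so the flag agrees with what the simulation goes on to do — and prior
breast cancer, 17.75). Funded testing requires one of: triple-negative
breast cancer at ≤50 (or any age with an affected relative), three or more
affected first/second-degree relatives, bilateral breast cancer, serous
grade 2–3 ovarian cancer, or non-mucinous grade 2–3 ovarian cancer under
70. Uptake is 0.96 (breast) / 0.95 (ovarian). The high-risk panel detects
BRCA1/2 and PALB2; the extended panel adds the other five genes.

**Cascade testing.** A first positive fixes the family variant and its
identification year. Eligibility is exact single-origin Mendelian
constraint propagation: a relative can still carry the variant iff some
founder is an ancestor-or-self of both the relative and every observed
carrier through links that are untested or positive. This one rule yields
both classic behaviours — a child of two tested-negative parents is an
obligate non-carrier, and a positive maternal grandfather makes the entire
paternal side ineligible. An exhaustive subset-enumeration oracle
(`enumerate_genotype_constraints()`) independently verifies the fast
implementation over generated pedigrees in the test suite. Annual uptake
follows the published grid by degree of relation to the nearest known
carrier (beyond-second-degree relatives use the second-degree rates), age
band, and time band since identification (`<1`, `1–3`, `>3` years, i.e.
cycle offsets 0; 1–3; 4+), with males at a rate ratio of 0.422 and
under-18s at zero. Each family tracks a single active variant: a second,
different-gene variant found later does not start a second cascade (a
prevalence-squared-order event).

**Screening and surgery.** Population mammography: ~30% never participate;
starters begin at 40–64 (mode 50) and rescreen two-yearly plus a small
geometric delay, to age 74, stopping at a personal breast-cancer history.
Identified carriers move to annual surveillance: mammography 25–64 plus MRI
25–59 for high-risk genes, mammography 35–59 for moderate-risk genes (start
age delayed ten years relative to high-risk). Combined-modality sensitivity
is `1 − Π(1 − sens)`. Known carriers may take risk-reducing mastectomy
(breast hazard ×0.10; PALB2 at the BRCA2 rate, ATM/CHEK2 at half, RAD51C/D
and BRIP1 ineligible) and salpingo-oophorectomy (ovarian hazard ×0.05;
eligibility from 35/40 for BRCA1/2, 45 for RAD51C/D, 50 for PALB2, 60 for
BRIP1). RRSO has no effect on breast-cancer risk by default
(`constants$rrso_breast_multiplier = 1`), a deliberately conservative
choice given the contested literature; it is switchable. Contralateral
mastectomy is offered at unilateral diagnosis with higher uptake for known
carriers, and removes contralateral risk only.

## Scenarios, common random numbers, and determinism

`build_scenario()` encodes: no testing (no high-risk management at all),
current practice, optimised referral (referral probability 1, eligibility
unchanged), and testing all breast cancers under 80 (modelled with uptake 1
for the universal offer, which is what reproduces near-complete proband
testing; the referral-pathway uptake stays 0.96/0.95). Interventions apply
to *all* individuals, so a family variant can first surface in a relative.

Every stochastic decision draws its uniform from a counter-based generator
keyed by (seed, person, process, year). Two consequences: runs are exactly
reproducible, and scenarios consume identical randomness person-by-person,
so setting every uptake to zero reproduces the no-testing scenario *bit for
bit*, and scenario contrasts are paired (the test suite checks both, plus
the nesting of tested probands across scenarios 2⊆3⊆4). The within-cycle
order is: ageing → births → death-time draws → onset/progression →
screening → diagnosis → referral + diagnostic testing (same year) →
knowledge update + predictive testing → risk pathway + surgery → death
resolution → exit. The true cycle order of the clinical systems being
emulated is not published at this granularity; this order is declared and
fixed rather than claimed authoritative.

## Outcome definitions

The analysis cohort is probands who develop breast cancer before 80,
excluding those whose variant was detected before diagnosis, plus their
relatives anchored at the proband's diagnosis year. Life expectancy is the
mean age at death (age-100 exit counts as 100); *anchored life-years* are
years lived after the anchor — both the level and the between-scenario
difference are reported, since "life-years saved" is ambiguous between
them. Cumulative incidence and surgery-uptake curves are discrete
product-limit estimates censoring at other-cause death, the competing
cancer, and exit (cross-checked against `survival::survfit` in the tests).

The five-year cascade-uptake statistic deserves its own definition, because
the natural candidates disagree. We fix the at-risk cohort at
identification: eligible relatives alive, cancer-unaffected and aged ≥18
that year. The headline uptake is the product-limit estimate over the five
cycles from identification, censoring members who leave the eligible pool
(death, panel testing after their own cancer, loss of eligibility through
lineage localisation); tests per family counts that cohort's tests divided
by identified families. A raw tested/alive-relatives ratio would be
substantially lower than the censored estimate while the tests-per-family
count stays ~2 — the pair of published figures is only mutually consistent
under a censored estimator over an adult unaffected cohort, which is why
this definition was chosen.

## What the defaults are, and are not

Published quantities (the referral odds model, testing uptake, the
predictive-uptake grid, the male rate ratio) are encoded verbatim. Every
other surface — gene frequencies, penetrance, baseline incidence,
lifetables, parity and maternal age, screening performance and
participation, sojourn parameters, tumour-characteristic and survival
tables, surgery uptake — is a literature-anchored stand-in, documented
per-table in `inst/extdata/hboc_defaults/provenance.md` and calibrated once
against published population summaries (family size ~22.3 for probands
50–54; ~30% never-screeners; non-carrier lifetime breast risk ~1 in 6.6 to
85 so that ~14% of non-carrier probands have a first-degree breast-cancer
history; prospective-cohort central penetrance for BRCA1/2/PALB2). The
synthetic generator therefore emulates the *aggregate* structure of an
Australian clinical-genetics family population; it does not reproduce
cohort effects (fertility and incidence are not calendar-year specific),
assortative mating, consanguinity, third-degree relatives, male cancers,
VUS reclassification, or privately funded testing. Passing tests show the
model is internally consistent and matches the published aggregates — not
that it predicts any particular clinic's caseload.

Population-validation summaries (family size, family-history prevalence)
are computed on probands aged 50–54, the age group the published
family-size figure refers to. Scenario analyses enter probands at 20–24 and
follow everyone to age 100 (up to 160 cycles).

## Numerical choices and problem sizes

Hazard tables are dense on integer ages; categorical draws use inverse-CDF
lookups; ties between competing events are broken by the uniform
within-year event times; the identification year uses the `<1 year` uptake
band. Degenerate inputs are honoured exactly (zero hazards produce no
events; a point-mass sojourn shifts diagnosis by exactly that many years;
an all-zero parity CDF collapses families to the forced seven members,
with the conditioned mother still granted the one child whose existence is
given). The packaged checks run at reduced scale chosen for tight
Monte-Carlo error at interactive runtimes: 10,000–20,000 families for
population summaries, 10,000 carrier-conditioned families for cascade
uptake, 20,000–40,000 families for scenario comparisons; the acceptance
script states the size used next to each quantity it reports.

## Known limitations

Ovarian cancer screening is deliberately absent. Treatment effects (PARP
inhibitors, systemic therapy differences by genotype) are not modelled, so
between-scenario survival differences flow only through earlier detection
and prevention. Carrier probability is rule-based rather than
pedigree-likelihood based. The appendix-level inputs of the system being
emulated are unavailable; where a published aggregate existed we calibrated
to it, and everything else is overridable through the parameter bundle.
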