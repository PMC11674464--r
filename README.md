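# hbocsim

A family-structured microsimulation of hereditary breast and ovarian cancer
(HBOC) genetic testing. The package is for epidemiologists and health-services
modellers who want to ask: *if Australia changed who gets germline testing
after a breast or ovarian cancer diagnosis, what would happen to cascade
testing in families, to risk-reducing surgery, and to cancer incidence and
life expectancy in relatives?*

## The model

Each simulated unit is a proband-centred family: a cancer-free woman plus her
first- and second-degree relatives (parents, grandparents, siblings,
children, piblings, niblings, grandchildren), generated from completed-parity
and maternal-age-at-birth distributions. Genotypes combine a single
pathogenic/likely pathogenic (P/LP) variant in one of eight genes (BRCA1,
BRCA2, PALB2, CHEK2 1100delC, ATM, RAD51C, RAD51D, BRIP1), transmitted
Mendelianly with no de novo events, and a polygenic score transmitted by the
infinitesimal model (child z = midparent mean + N(0, 1/2)).

Cancer natural history runs in yearly cycles. The per-year onset probability
for organ *o* at age *a* is

    1 − exp(−h_g,o(a) · HR_o^z / E[HR_o^z])

where *h_g,o* is the genotype-specific hazard curve and *HR_o* the hazard
ratio per SD of polygenic score (normalised so the population-average
multiplier is 1). Breast cancer has a preclinical, screen-detectable phase
with a lognormal sojourn time; ovarian cancer has none. Tumour subtype,
grade, size, nodes and stage are drawn from conditional tables; survival
follows annual excess-mortality rates by organ, stage and time since
diagnosis, competing with a cause-deleted lifetable.

Clinical pathways: referral to genetics services happens only in a diagnosis
year, with probability `odds/(1+odds)` from a published odds model (constant
3.23 for breast, 3.09 for ovarian, with odds ratios for age, grade, subtype,
survival under 12 months and prior breast cancer). Publicly funded testing
requires the 10% carrier-probability criteria; relatives of a known carrier
take predictive tests at published annual probabilities by degree, age band
and time since the family variant was identified (males at a rate ratio of
0.422), with obligate non-carriers and off-lineage branches excluded by
exact constraint propagation. Identified carriers enter high- or
moderate-risk surveillance and may take risk-reducing mastectomy (hazard
×0.10) or salpingo-oophorectomy (ovarian hazard ×0.05).

Four scenarios are built in: `no_testing`, `current_practice`,
`optimised_referral` (referral probability 1), and `test_all_breast`
(testing for every breast cancer diagnosed before 80). All stochastic draws
are counter-based per (person, process, year), so scenarios run under common
random numbers and are directly comparable.

## A worked example

```r
library(hbocsim)

p   <- default_parameters()
pop <- generate_population(2000, p, proband_age_group = c(20, 24), seed = 1)

s1 <- run_simulation(pop, build_scenario("no_testing", seed = 1), p)
s2 <- run_simulation(pop, build_scenario("current_practice", seed = 1), p)

glance(s2)
#> # A tibble: 1 x 11
#>   scenario         n_persons n_families n_breast n_ovarian n_panel_tests
#>   <chr>                <int>      <int>    <int>     <int>         <int>
#> 1 current_practice     62896       2000     4038       371           251
#> # n_predictive_tests 131, n_positive 63, n_brrm 10, n_rrso 30,
#> # n_variant_families 27

summary_report(list(none = s1, current = s2)) |>
  write_outcomes("outcomes")          # outcomes.csv + outcomes.md
```

`glance()` gives one row per run: with 2,000 families (~63,000 persons
followed to age 100), 4,038 develop breast cancer and 371 ovarian cancer;
current practice performs 251 diagnostic panel tests — the women whose
tumours meet the referral and funding criteria — finds a family variant in
27 families, and the cascade adds 131 predictive tests, 63 positives, and
40 risk-reducing surgeries. `summary_report()` assembles the cross-scenario table: proband counts,
carrier prevalence, test counts with percentages, secondary ovarian cancers
in carriers, relatives alive per carrier proband, and life expectancy plus
anchored life-years with confidence intervals. `tidy(sim)` returns the long
event log; `select_cohort()`, `detection_rate()`, `life_metrics()` and
`incidence_and_uptake_curves()` (with `autoplot()`) compute the analysis
cohort and its outcome metrics.

A command-line wrapper for single runs is installed at
`system.file("cli", "run_simulation.R", package = "hbocsim")`.

## Parameters

`default_parameters()` loads the bundled parameter set
(`inst/extdata/hboc_defaults/`): one YAML config referencing plain CSV
tables. Published referral/uptake values are encoded verbatim; hazard
curves, family-structure distributions, screening performance and tumour
models are literature-anchored stand-ins documented in the bundle's
`provenance.md`. Any table can be overridden from a user YAML config via
`load_parameters()`; `validate_parameters()` reports structural problems,
and `write_parameters()` round-trips a set to disk.

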