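# Generates the default parameter bundle CSVs under inst/extdata/hboc_defaults.
# Run from the repository root: Rscript tools/make_bundle.R
suppressPackageStartupMessages({ library(readr); library(tibble); library(yaml); library(purrr); library(dplyr) })

out <- "inst/extdata/hboc_defaults"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

GENES <- c("BRCA1","BRCA2","PALB2","CHEK2_1100delC","ATM","RAD51C","RAD51D","BRIP1")

# ---- gene prevalences (population carrier frequencies) ----
genes <- tibble(gene = GENES,
                prevalence = c(0.0020, 0.0030, 0.0020, 0.0026, 0.0050,
                               0.0008, 0.0005, 0.0010))
write_csv(genes, file.path(out, "genes.csv"))

# ---- hazard curves from cumulative-risk knots ----
# piecewise-constant annual hazards on integer ages, by differencing the
# cumulative risk then -log(1 - .)
haz_from_knots <- function(knot_age, knot_F) {
  stopifnot(knot_age[1] == 0, knot_F[1] == 0, tail(knot_age, 1) == 100)
  h <- numeric(101)
  H <- -log(1 - knot_F)
  for (i in seq_len(length(knot_age) - 1)) {
    a0 <- knot_age[i]; a1 <- knot_age[i + 1]
    h[(a0:(a1 - 1)) + 1] <- (H[i + 1] - H[i]) / (a1 - a0)
  }
  h[101] <- h[100]
  round(h, 8)
}

breast_base <- haz_from_knots(
  c(0, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 100),
  c(0, 1e-4, 4e-4, 0.0015, 0.0045, 0.011, 0.020, 0.031, 0.0455, 0.0615,
    0.080, 0.098, 0.118, 0.137, 0.152, 0.162, 0.172))
ovary_base <- haz_from_knots(
  c(0, 30, 40, 50, 60, 70, 80, 90, 100),
  c(0, 1e-4, 5e-4, 0.0016, 0.0038, 0.0071, 0.0103, 0.0123, 0.013))
baseline_incidence <- bind_rows(
  tibble(organ = "breast", age = 0:100, hazard = breast_base),
  tibble(organ = "ovary", age = 0:100, hazard = ovary_base))
write_csv(baseline_incidence, file.path(out, "baseline_incidence.csv"))

# carrier penetrance: explicit knot curves for high-risk genes, relative-risk
# scaling of the baseline for the moderate-risk genes
pen_curves <- list(
  breast = list(
    BRCA1 = haz_from_knots(c(0, 20, 25, 30, 40, 50, 60, 70, 80, 100),
                           c(0, 0, 0.008, 0.035, 0.20, 0.39, 0.54, 0.64, 0.72, 0.75)),
    BRCA2 = haz_from_knots(c(0, 20, 25, 30, 40, 50, 60, 70, 80, 100),
                           c(0, 0, 0.004, 0.02, 0.11, 0.26, 0.46, 0.61, 0.69, 0.73)),
    PALB2 = haz_from_knots(c(0, 25, 30, 40, 50, 60, 70, 80, 100),
                           c(0, 0, 0.015, 0.07, 0.17, 0.33, 0.44, 0.53, 0.55)),
    CHEK2_1100delC = breast_base * 2.0,
    ATM = breast_base * 2.1,
    RAD51C = breast_base * 1.6,
    RAD51D = breast_base * 1.6,
    BRIP1 = breast_base
  ),
  ovary = list(
    BRCA1 = haz_from_knots(c(0, 30, 40, 50, 60, 70, 80, 100),
                           c(0, 0, 0.03, 0.15, 0.30, 0.40, 0.44, 0.45)),
    BRCA2 = haz_from_knots(c(0, 40, 50, 60, 70, 80, 100),
                           c(0, 0.005, 0.03, 0.09, 0.14, 0.17, 0.18)),
    PALB2 = haz_from_knots(c(0, 40, 50, 60, 70, 80, 100),
                           c(0, 0.001, 0.008, 0.02, 0.035, 0.05, 0.055)),
    CHEK2_1100delC = ovary_base,
    ATM = ovary_base * 1.3,
    RAD51C = haz_from_knots(c(0, 40, 50, 60, 70, 80, 100),
                            c(0, 0.002, 0.015, 0.05, 0.09, 0.11, 0.12)),
    RAD51D = haz_from_knots(c(0, 40, 50, 60, 70, 80, 100),
                            c(0, 0.002, 0.02, 0.06, 0.11, 0.13, 0.14)),
    BRIP1 = haz_from_knots(c(0, 45, 50, 60, 70, 80, 100),
                           c(0, 0.002, 0.006, 0.02, 0.045, 0.065, 0.07))
  )
)
# carriers never fall below population risk
base_of <- list(breast = breast_base, ovary = ovary_base)
penetrance <- map_dfr(c("breast", "ovary"), function(org) {
  map_dfr(GENES, function(g) {
    tibble(gene = g, organ = org, age = 0:100,
           hazard = round(pmax(pen_curves[[org]][[g]], base_of[[org]]), 8))
  })
})
write_csv(penetrance, file.path(out, "penetrance.csv"))

write_csv(tibble(organ = c("breast", "ovary"), hr_per_sd = c(1.6, 1.3)),
          file.path(out, "polygenic.csv"))

# ---- referral model and uptake (verbatim published values) ----
referral <- tribble(
  ~cancer, ~term, ~or,
  "breast", "constant", 3.23,
  "breast", "age_40_49", 0.38,
  "breast", "age_50_69", 0.22,
  "breast", "age_70p", 0.10,
  "breast", "survival_lt12m", 0.35,
  "breast", "high_grade", 2.37,
  "breast", "non_tn", 0.50,
  "breast", "her2", 0.22,
  "ovary", "constant", 3.09,
  "ovary", "age_60_74", 0.20,
  "ovary", "age_75p", 0.08,
  "ovary", "survival_lt12m", 0.04,
  "ovary", "high_grade", 1.06,
  "ovary", "prior_breast", 17.75,
  "ovary", "mucinous", 0.08,
  "ovary", "other_hist", 0.20)
write_csv(referral, file.path(out, "referral.csv"))

write_csv(tibble(cancer = c("breast", "ovary"), uptake = c(0.96, 0.95)),
          file.path(out, "testing_uptake.csv"))

pred <- expand.grid(degree = c(1L, 2L),
                    age_band = c("<18", "18-29", "30-49", "50-59", "60+"),
                    time_band = c("<1", "1-3", ">3"),
                    stringsAsFactors = FALSE) |> as_tibble() |> arrange(degree)
vals1 <- matrix(c(0, 0, 0,
                  0.259, 0.098, 0.071,
                  0.286, 0.098, 0.022,
                  0.146, 0.033, 0.010,
                  0.099, 0.014, 0.007), ncol = 3, byrow = TRUE)
vals2 <- matrix(c(0, 0, 0,
                  0.072, 0.045, 0.034,
                  0.112, 0.080, 0.021,
                  0.114, 0.034, 0.002,
                  0.039, 0.017, 0.002), ncol = 3, byrow = TRUE)
bands <- c("<18", "18-29", "30-49", "50-59", "60+")
tbands <- c("<1", "1-3", ">3")
pred$prob <- mapply(function(d, a, t) {
  v <- if (d == 1) vals1 else vals2
  v[match(a, bands), match(t, tbands)]
}, pred$degree, pred$age_band, pred$time_band)
write_csv(pred, file.path(out, "predictive_uptake.csv"))

# ---- family structure ----
parity_completed <- tibble(children = 0:8,
                           cdf = c(0.15, 0.28, 0.53, 0.74, 0.87, 0.94, 0.975, 0.99, 1))
write_csv(parity_completed, file.path(out, "parity_completed.csv"))

mat_age <- tibble(age = 16:45)
mat_age$prob <- dnorm(mat_age$age, 26.5, 5.5)
mat_age$prob <- round(mat_age$prob / sum(mat_age$prob), 8)
mat_age$prob[which.max(mat_age$prob)] <- mat_age$prob[which.max(mat_age$prob)] +
  (1 - sum(mat_age$prob))
write_csv(mat_age, file.path(out, "maternal_age.csv"))

# age-specific parity CDFs implied by completed parity + maternal-age schedule
pk <- diff(c(0, parity_completed$cdf))
groups <- tibble(age_group = c("0-19","20-24","25-29","30-34","35-39","40-44","45+"),
                 mid = c(18, 22, 27, 32, 37, 42, 47))
parity_age <- map_dfr(seq_len(nrow(groups)), function(g) {
  fa <- sum(mat_age$prob[mat_age$age <= groups$mid[g]])
  fa <- min(1, fa)
  pn <- vapply(0:8, function(nb)
    sum(vapply(nb:8, function(k) pk[k + 1] * dbinom(nb, k, fa), numeric(1))),
    numeric(1))
  tibble(age_group = groups$age_group[g], children = 0:8,
         cdf = round(pmin(1, cumsum(pn) / sum(pn)), 8))
})
parity_age$cdf[parity_age$children == 8] <- 1
write_csv(parity_age, file.path(out, "parity_age.csv"))

# ---- lifetables (Gompertz-Makeham stand-ins, female net of breast/ovary) ----
qx_f <- pmin(0.65, 2e-4 + 8e-6 * exp(0.105 * (0:100)))
qx_f[1] <- 0.004; qx_f[2:11] <- 1e-4
qx_m <- pmin(0.70, 4e-4 + 1.6e-5 * exp(0.103 * (0:100)))
qx_m[1] <- 0.005; qx_m[2:11] <- 1.5e-4
lifetable <- bind_rows(tibble(sex = "F", age = 0:100, qx = round(qx_f, 7)),
                       tibble(sex = "M", age = 0:100, qx = round(qx_m, 7)))
write_csv(lifetable, file.path(out, "lifetable.csv"))

# ---- screening ----
screening_performance <- tribble(
  ~modality, ~age_lo, ~age_hi, ~sens, ~spec,
  "mammography", 0L, 39L, 0.60, 0.94,
  "mammography", 40L, 49L, 0.75, 0.95,
  "mammography", 50L, 59L, 0.85, 0.96,
  "mammography", 60L, 100L, 0.88, 0.97,
  "mri", 0L, 100L, 0.90, 0.88)
write_csv(screening_performance, file.path(out, "screening_performance.csv"))

screening_start <- tibble(
  age = 40:64,
  prob = c(rep(0.03, 5), rep(0.02, 5), 0.30, rep(0.05, 4), rep(0.03, 5), rep(0.02, 5)))
stopifnot(abs(sum(screening_start$prob) - 1) < 1e-9)
write_csv(screening_start, file.path(out, "screening_start.csv"))

screening_delay <- bind_rows(
  tibble(context = "population", years = 0:3, prob = c(0.70, 0.20, 0.07, 0.03)),
  tibble(context = "highrisk_start", years = 0:3, prob = c(0.50, 0.25, 0.15, 0.10)),
  tibble(context = "highrisk_interval", years = 0:3, prob = c(0.75, 0.15, 0.07, 0.03)))
write_csv(screening_delay, file.path(out, "screening_delay.csv"))

# ---- risk-reducing surgery ----
brrm_b2 <- tribble(~age_lo, ~age_hi, ~annual_prob,
                   18L, 39L, 0.045, 40L, 49L, 0.030, 50L, 59L, 0.015, 60L, 100L, 0.005)
surgery_uptake <- bind_rows(
  brrm_b2 |> mutate(surgery = "BRRM", gene = "BRCA1"),
  brrm_b2 |> mutate(surgery = "BRRM", gene = "BRCA2"),
  brrm_b2 |> mutate(surgery = "BRRM", gene = "PALB2"),
  brrm_b2 |> mutate(surgery = "BRRM", gene = "ATM", annual_prob = annual_prob / 2),
  brrm_b2 |> mutate(surgery = "BRRM", gene = "CHEK2_1100delC", annual_prob = annual_prob / 2),
  tribble(~age_lo, ~age_hi, ~annual_prob, 35L, 44L, 0.07, 45L, 54L, 0.11, 55L, 100L, 0.05) |>
    mutate(surgery = "RRSO", gene = "BRCA1"),
  tribble(~age_lo, ~age_hi, ~annual_prob, 40L, 44L, 0.06, 45L, 54L, 0.10, 55L, 100L, 0.05) |>
    mutate(surgery = "RRSO", gene = "BRCA2"),
  tribble(~age_lo, ~age_hi, ~annual_prob, 50L, 54L, 0.10, 55L, 100L, 0.05) |>
    mutate(surgery = "RRSO", gene = "PALB2"),
  tribble(~age_lo, ~age_hi, ~annual_prob, 45L, 54L, 0.10, 55L, 100L, 0.05) |>
    mutate(surgery = "RRSO", gene = "RAD51C"),
  tribble(~age_lo, ~age_hi, ~annual_prob, 45L, 54L, 0.10, 55L, 100L, 0.05) |>
    mutate(surgery = "RRSO", gene = "RAD51D"),
  tribble(~age_lo, ~age_hi, ~annual_prob, 60L, 100L, 0.05) |>
    mutate(surgery = "RRSO", gene = "BRIP1")) |>
  select(surgery, gene, age_lo, age_hi, annual_prob)
write_csv(surgery_uptake, file.path(out, "surgery_uptake.csv"))

# ---- survival (annual excess mortality by organ x stage x years since dx) ----
survival_excess <- tribble(
  ~organ, ~stage, ~yrs_lo, ~yrs_hi, ~rate,
  "breast", "local", 0L, 4L, 0.005, "breast", "local", 5L, 9L, 0.003,
  "breast", "local", 10L, 100L, 0.001,
  "breast", "regional", 0L, 4L, 0.030, "breast", "regional", 5L, 9L, 0.018,
  "breast", "regional", 10L, 100L, 0.007,
  "breast", "distant", 0L, 4L, 0.250, "breast", "distant", 5L, 9L, 0.150,
  "breast", "distant", 10L, 100L, 0.070,
  "ovary", "local", 0L, 4L, 0.020, "ovary", "local", 5L, 9L, 0.012,
  "ovary", "local", 10L, 100L, 0.005,
  "ovary", "regional", 0L, 4L, 0.090, "ovary", "regional", 5L, 9L, 0.050,
  "ovary", "regional", 10L, 100L, 0.020,
  "ovary", "distant", 0L, 4L, 0.300, "ovary", "distant", 5L, 9L, 0.180,
  "ovary", "distant", 10L, 100L, 0.080)
write_csv(survival_excess, file.path(out, "survival_excess.csv"))

survival_modifiers <- tribble(
  ~type, ~level, ~multiplier,
  "histology", "serous", 1.1, "histology", "clear_cell", 1.2,
  "histology", "endometrioid", 0.7, "histology", "mucinous", 0.8,
  "histology", "other", 1.0,
  "age", "<50", 0.85, "age", "50-69", 1.0, "age", "70+", 1.3)
write_csv(survival_modifiers, file.path(out, "survival_modifiers.csv"))

# ---- tumour models ----
breast_subtype <- bind_rows(
  tibble(gene = "none", subtype = c("TN", "HER2", "HRplus"), prob = c(0.11, 0.13, 0.76)),
  tibble(gene = "BRCA1", subtype = c("TN", "HER2", "HRplus"), prob = c(0.61, 0.05, 0.34)),
  tibble(gene = "BRCA2", subtype = c("TN", "HER2", "HRplus"), prob = c(0.16, 0.05, 0.79)),
  tibble(gene = "PALB2", subtype = c("TN", "HER2", "HRplus"), prob = c(0.30, 0.05, 0.65)),
  tibble(gene = "CHEK2_1100delC", subtype = c("TN", "HER2", "HRplus"), prob = c(0.05, 0.10, 0.85)),
  tibble(gene = "ATM", subtype = c("TN", "HER2", "HRplus"), prob = c(0.05, 0.10, 0.85)),
  tibble(gene = "RAD51C", subtype = c("TN", "HER2", "HRplus"), prob = c(0.30, 0.10, 0.60)),
  tibble(gene = "RAD51D", subtype = c("TN", "HER2", "HRplus"), prob = c(0.30, 0.10, 0.60)),
  tibble(gene = "BRIP1", subtype = c("TN", "HER2", "HRplus"), prob = c(0.11, 0.13, 0.76)))
write_csv(breast_subtype, file.path(out, "breast_subtype.csv"))

breast_grade <- bind_rows(
  tibble(subtype = "TN", grade = 1:3, prob = c(0.03, 0.17, 0.80)),
  tibble(subtype = "HER2", grade = 1:3, prob = c(0.10, 0.40, 0.50)),
  tibble(subtype = "HRplus", grade = 1:3, prob = c(0.30, 0.50, 0.20)))
write_csv(breast_grade, file.path(out, "breast_grade.csv"))

breast_size <- bind_rows(
  tibble(mode = "screen", size_class = c("<=10", "11-20", "21-50", ">50"),
         prob = c(0.45, 0.40, 0.13, 0.02)),
  tibble(mode = "symptomatic", size_class = c("<=10", "11-20", "21-50", ">50"),
         prob = c(0.15, 0.40, 0.38, 0.07)),
  tibble(mode = "baseline", size_class = c("<=10", "11-20", "21-50", ">50"),
         prob = c(0.15, 0.40, 0.38, 0.07)))
write_csv(breast_size, file.path(out, "breast_size.csv"))

write_csv(tibble(size_class = c("<=10", "11-20", "21-50", ">50"),
                 p_pos = c(0.12, 0.25, 0.45, 0.65)),
          file.path(out, "breast_nodes.csv"))
write_csv(tibble(nodes = c("negative", "positive"), p_met = c(0.01, 0.08)),
          file.path(out, "breast_met.csv"))

ovarian_histology <- bind_rows(
  tibble(age_band = "<50", histology = c("serous", "endometrioid", "clear_cell", "mucinous", "other"),
         prob = c(0.35, 0.25, 0.15, 0.15, 0.10)),
  tibble(age_band = "50-69", histology = c("serous", "endometrioid", "clear_cell", "mucinous", "other"),
         prob = c(0.50, 0.18, 0.10, 0.10, 0.12)),
  tibble(age_band = "70+", histology = c("serous", "endometrioid", "clear_cell", "mucinous", "other"),
         prob = c(0.60, 0.10, 0.05, 0.08, 0.17)))
write_csv(ovarian_histology, file.path(out, "ovarian_histology.csv"))

ovarian_grade <- bind_rows(
  tibble(histology = "serous", grade = 1:3, prob = c(0.10, 0.20, 0.70)),
  tibble(histology = "endometrioid", grade = 1:3, prob = c(0.30, 0.40, 0.30)),
  tibble(histology = "clear_cell", grade = 1:3, prob = c(0.05, 0.35, 0.60)),
  tibble(histology = "mucinous", grade = 1:3, prob = c(0.55, 0.30, 0.15)),
  tibble(histology = "other", grade = 1:3, prob = c(0.20, 0.30, 0.50)))
write_csv(ovarian_grade, file.path(out, "ovarian_grade.csv"))

# stage | histology + grade: distant probability rises with grade and with
# serous histology
ovarian_stage <- map_dfr(unique(ovarian_grade$histology), function(h) {
  map_dfr(1:3, function(g) {
    p_dist <- 0.15 + 0.12 * (g - 1) + 0.20 * (h == "serous")
    p_loc <- max(0.08, 0.55 - 0.12 * (g - 1) - 0.20 * (h == "serous"))
    p_reg <- 1 - p_dist - p_loc
    tibble(histology = h, grade = g, stage = c("local", "regional", "distant"),
           prob = round(c(p_loc, p_reg, p_dist), 6))
  })
})
write_csv(ovarian_stage, file.path(out, "ovarian_stage.csv"))

# ---- preclinical sojourn (lognormal years) ----
sojourn <- tibble(
  gene = c("none", GENES),
  meanlog = round(log(c(3.0, 1.8, 2.5, 2.5, 3.0, 3.0, 3.0, 3.0, 3.0)), 6),
  sdlog = c(0.55, 0.50, 0.50, 0.50, 0.55, 0.55, 0.55, 0.55, 0.55))
write_csv(sojourn, file.path(out, "sojourn.csv"))

# ---- config + constants ----
tables <- c("genes", "baseline_incidence", "penetrance", "polygenic", "referral",
            "testing_uptake", "predictive_uptake", "parity_completed", "parity_age",
            "maternal_age", "lifetable", "screening_performance", "screening_start",
            "screening_delay", "surgery_uptake", "survival_excess",
            "survival_modifiers", "breast_subtype", "breast_grade", "breast_size",
            "breast_nodes", "breast_met", "ovarian_histology", "ovarian_grade",
            "ovarian_stage", "sojourn")
cfg <- list(
  tables = as.list(setNames(paste0(tables, ".csv"), tables)),
  constants = list(
    male_rate_ratio = 0.422,
    max_children = 8L,
    never_screen = 0.30,
    polygenic_corr = 0,
    brrm_multiplier = 0.10,
    rrso_ovary_multiplier = 0.05,
    rrso_breast_multiplier = 1.0,
    crrm_uptake_carrier = 0.35,
    crrm_uptake_noncarrier = 0.05,
    nodes_screen_multiplier = 0.70,
    pop_screen_interval = 2L,
    hr_screen_interval = 1L,
    pop_screen_stop = 74L,
    pop_start_lo = 40L, pop_start_hi = 64L,
    hr_mammo_lo = 25L, hr_mammo_hi = 64L,
    hr_mri_lo = 25L, hr_mri_hi = 59L,
    mod_mammo_lo = 35L, mod_mammo_hi = 59L,
    moderate_start_delay = 10L,
    spouse_gap_mean = 2, spouse_gap_sd = 3,
    paternal_shift = 2L
  )
)
write_yaml(cfg, file.path(out, "config.yaml"))

cat("bundle written to", out, "\n")
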