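person_row <- function(gene = 0L, zb = 0, zo = 0, female = TRUE, id = 1L, ...) {
  tibble::tibble(id = id, gene = gene, zb = zb, zo = zo, female = female, ...)
}

test_that("population-average hazard recovers the baseline table", {
  pp <- the_params
  base <- pp$baseline_incidence
  hr_b <- pp$polygenic$hr_per_sd[pp$polygenic$organ == "breast"]
  norm_b <- exp(log(hr_b)^2 / 2)
  # Gauss-Hermite-style quadrature over z ~ N(0,1): the polygenic
  # multiplier averages to exactly one across the population
  z <- qnorm(seq(0.0005, 0.9995, by = 0.001))
  expect_lt(abs(mean(exp(log(hr_b) * z)) / norm_b - 1), 1e-3)
  for (a in c(30, 45, 60, 80)) {
    h0 <- base$hazard[base$organ == "breast" & base$age == a]
    hz <- -log(1 - annual_hazard(person_row(zb = z), "breast", a, pp))
    expect_lt(abs(mean(hz) - h0), h0 * 2e-3 + 1e-10)
    # at z = 0 the hazard is the baseline divided by the normaliser
    expect_equal(annual_hazard(person_row(), "breast", a, pp),
                 1 - exp(-h0 / norm_b), tolerance = 1e-12)
  }
  expect_identical(annual_hazard(person_row(female = FALSE), "breast", 50, pp), 0)
  expect_error(annual_hazard(person_row(), "breast", 101, pp), "0-100")
})

test_that("the polygenic multiplier scales hazards by HR per SD", {
  pp <- the_params
  hr <- pp$polygenic$hr_per_sd[pp$polygenic$organ == "breast"]
  h1 <- -log(1 - annual_hazard(person_row(zb = 1), "breast", 50, pp))
  h0 <- -log(1 - annual_hazard(person_row(zb = 0), "breast", 50, pp))
  expect_equal(h1 / h0, hr, tolerance = 1e-10)
})

test_that("risk-reducing surgery multiplies hazards by the residual factor", {
  pp <- the_params
  pre <- -log(1 - annual_hazard(person_row(gene = 1L), "breast", 45, pp))
  post <- -log(1 - annual_hazard(person_row(gene = 1L, brrm_age = 40),
                                 "breast", 45, pp))
  expect_equal(post / pre, pp$constants$brrm_multiplier, tolerance = 1e-10)
  preo <- -log(1 - annual_hazard(person_row(gene = 1L), "ovary", 45, pp))
  posto <- -log(1 - annual_hazard(person_row(gene = 1L, rrso_age = 40),
                                  "ovary", 45, pp))
  expect_equal(posto / preo, pp$constants$rrso_ovary_multiplier,
               tolerance = 1e-10)
  # surgery in the future does not apply yet
  expect_equal(annual_hazard(person_row(gene = 1L, brrm_age = 50), "breast",
                             45, pp),
               annual_hazard(person_row(gene = 1L), "breast", 45, pp))
})

test_that("carrier hazards dominate non-carrier hazards at every age", {
  pen <- the_params$penetrance
  base <- the_params$baseline_incidence
  for (g in c("BRCA1", "BRCA2", "PALB2", "ATM")) {
    hb <- pen$hazard[pen$gene == g & pen$organ == "breast"]
    expect_true(all(hb >= base$hazard[base$organ == "breast"] - 1e-12))
  }
})

test_that("zero hazards produce no tumour; a degenerate sojourn is exact", {
  toy <- make_toy_population("no_cancer_world", n_families = 1, seed = 5)
  pro <- toy$population[toy$population$rel == "proband", ]
  pro$age <- pro$age_entry
  expect_identical(nrow(sample_breast_course(pro, toy$params, seed = 5)), 0L)

  spike <- make_toy_population("certain_cancer_proband", n_families = 1,
                               seed = 5)
  pro <- spike$population[spike$population$rel == "proband", ]
  pro$age <- pro$age_entry
  course <- sample_breast_course(pro, spike$params, seed = 5)
  expect_identical(nrow(course), 1L)
  expect_true(course$age_at_onset >= 45 & course$age_at_onset < 46)
  expect_equal(course$sojourn_time, 2)
  expect_equal(course$age_at_diagnosis, course$age_at_onset + 2)
})

test_that("BRRM precludes a breast course and RRSO precludes ovarian cancer", {
  spike <- make_toy_population("certain_cancer_proband", n_families = 1,
                               seed = 5)
  pro <- spike$population[spike$population$rel == "proband", ]
  pro$age <- pro$age_entry
  pro$brrm_age <- 30
  expect_error(sample_breast_course(pro, spike$params, seed = 5), "mastectomy")
  pro2 <- spike$population[spike$population$rel == "proband", ]
  pro2$rrso_age <- 40
  expect_identical(nrow(sample_ovarian_cancer(pro2, 45, spike$params)), 0L)
})

test_that("genotype drives the breast subtype mix", {
  spike <- make_toy_population("certain_cancer_proband", n_families = 1,
                               seed = 5)
  spp <- hbocsim:::prepare_params(spike$params)
  subtype_of <- function(gene, ids) {
    vapply(ids, function(i) {
      pr <- person_row(gene = gene, id = i)
      pr$age <- 30
      sample_breast_course(pr, spp, seed = 11)$subtype
    }, character(1))
  }
  n <- 400
  tn_brca1 <- mean(subtype_of(1L, seq_len(n)) == "TN")
  tn_none <- mean(subtype_of(0L, seq_len(n) + n) == "TN")
  expect_gt(tn_brca1, tn_none + 0.2)
})

test_that("prognostic characteristics are immutable and mode-dependent", {
  t1 <- tibble::tibble(person_id = 1L, gene = 0L, age_at_diagnosis = 55)
  t1 <- assign_breast_prognostics(t1, "screen", the_params, seed = 3)
  expect_true(t1$size_class %in% c("<=10", "11-20", "21-50", ">50"))
  expect_error(assign_breast_prognostics(t1, "screen", the_params, seed = 3),
               "fixed")
  # screen-detected tumours are stochastically smaller than symptomatic
  tpp <- hbocsim:::prepare_params(the_params)
  size_rank <- function(mode) {
    cls <- c("<=10", "11-20", "21-50", ">50")
    vapply(1:800, function(i) {
      tt <- tibble::tibble(person_id = i, gene = 0L, age_at_diagnosis = 60)
      match(assign_breast_prognostics(tt, mode, tpp, seed = 7)$size_class,
            cls)
    }, numeric(1))
  }
  expect_lt(mean(size_rank("screen")), mean(size_rank("symptomatic")) - 0.2)
})

test_that("carrier ovarian cancers after 25 are high-grade serous", {
  pr <- person_row(gene = 1L)
  rec <- sample_ovarian_cancer(pr, 52, the_params, seed = 2)
  expect_identical(rec$histology, "serous")
  expect_identical(rec$grade, 3L)
  # advanced stage is more likely for high-grade serous than low-grade
  # mucinous under the default conditional tables
  os <- the_params$ovarian_stage
  p_d <- function(h, g) os$prob[os$histology == h & os$grade == g &
                                  os$stage == "distant"]
  expect_gt(p_d("serous", 3), p_d("mucinous", 1))
})

test_that("death follows the lifetable and stops at the age-100 cap", {
  p <- the_params
  p$lifetable$qx <- ifelse(p$lifetable$age == 90, 1, 0)
  pr <- person_row()
  pr$age <- 70
  d <- sample_death(pr, p, seed = 4)
  expect_identical(d$age_at_death, 90)
  expect_identical(d$cause, "other")
  p$lifetable$qx <- rep(0, nrow(p$lifetable))
  d2 <- sample_death(pr, p, seed = 4)
  expect_identical(d2$age_at_death, 100)
  expect_identical(d2$cause, "exit")
  # zeroed cancer survival tables mean no cancer deaths
  p$survival_excess$rate <- 0
  pr$bc1_age0 <- 60; pr$bc1_stage0 <- 3L
  d3 <- sample_death(pr, p, seed = 4)
  expect_identical(d3$cause, "exit")
})

test_that("simulated survival recovers the excess-mortality input", {
  p <- the_params
  p$lifetable$qx <- rep(0, nrow(p$lifetable))  # isolate the excess hazard
  ppp <- hbocsim:::prepare_params(p)
  n <- 3000
  surv5 <- vapply(seq_len(n), function(i) {
    pr <- person_row(id = i)
    pr$age <- 60; pr$bc1_age0 <- 60; pr$bc1_stage0 <- 2L
    sample_death(pr, ppp, seed = 9)$age_at_death >= 65
  }, logical(1))
  rate <- p$survival_excess$rate[p$survival_excess$organ == "breast" &
                                   p$survival_excess$stage == "regional" &
                                   p$survival_excess$yrs_lo == 0]
  mult <- 1  # age 60 is in the reference 50-69 band
  expected <- prod((1 - (1 - exp(-rate * mult)))^5)
  expect_lt(abs(mean(surv5) - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("non-carrier lifetime incidence recovers the input table", {
  # independent women, no competing mortality, long horizon
  n <- 8000
  set.seed(4242)
  pop <- tibble::tibble(
    id = seq_len(n), fam = seq_len(n), rel = "proband", female = TRUE,
    member = TRUE, mother = NA_integer_, father = NA_integer_,
    age_entry = 20, gene = 0L, zb = rnorm(n), zo = rnorm(n),
    never_born = FALSE, alive0 = "alive", death_age0 = NA_real_,
    death_cause0 = NA_character_, bc1_age0 = NA_real_,
    bc1_stage0 = NA_integer_, bc2_age0 = NA_real_, oc_age0 = NA_real_,
    oc_stage0 = NA_integer_, oc_hist0 = NA_character_, bc_pre0 = FALSE,
    bc_onset0 = NA_real_, bc_expiry0 = NA_real_)
  class(pop) <- c("hboc_population", class(tibble::tibble()))
  p <- the_params
  p$lifetable$qx <- rep(0, nrow(p$lifetable))
  p$survival_excess$rate <- 0
  p$constants$never_screen <- 1  # no screening: symptomatic detection only
  sim <- run_simulation(pop, build_scenario("no_testing", seed = 77,
                                            horizon = 90), p)
  po <- sim$population
  H <- p$baseline_incidence
  cum_to <- function(a) {
    1 - exp(-sum(H$hazard[H$organ == "breast" & H$age < a]))
  }
  # diagnosis lags onset by the sojourn; compare diagnosed-by-80 with
  # onset-by-77 (median sojourn 3 years) within Monte-Carlo tolerance
  sim_cum80 <- mean(!is.na(po$bc1_age) & po$bc1_age <= 80)
  expect_lt(abs(sim_cum80 - cum_to(77)), 0.015)
  # ovarian: no preclinical lag at all
  sim_oc <- mean(!is.na(po$oc_age) & po$oc_age <= 80)
  Ho <- 1 - exp(-sum(H$hazard[H$organ == "ovary" & H$age < 80]))
  ho_expect <- Ho  # ovarian hazards are small; overlap with breast ignored
  expect_lt(abs(sim_oc - ho_expect), 0.006)
})
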