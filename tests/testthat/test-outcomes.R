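# hand-built simulation objects for outcome-arithmetic checks

fake_sim <- function(po, fam_gene = integer(max(po$fam)),
                     fam_year = rep(NA_integer_, max(po$fam))) {
  structure(list(population = po, fam_gene = fam_gene, fam_year = fam_year,
                 cascade = list(risk = numeric(5), tests = numeric(5),
                                denom = 0, tests5_member = 0, tests5_all = 0,
                                member_risk = numeric(5),
                                member_tests = numeric(5)),
                 scenario = build_scenario("no_testing"), n_cycles = 160L),
            class = "hboc_sim")
}

base_person <- function(id, fam, rel, ...) {
  tibble::tibble(
    id = id, fam = fam, rel = rel, female = TRUE, member = TRUE, gene = 0L,
    age_entry = 20, alive = FALSE, exited = FALSE, death_age = 90,
    death_year = 70L, death_cause = "other", never_born = FALSE,
    unborn_left = FALSE, bc1_age = NA_real_, bc1_year = NA_integer_,
    bc1_stage = NA_integer_, bc1_mode = NA_character_,
    bc1_subtype = NA_character_, bc2_age = NA_real_, bc2_year = NA_integer_,
    oc_age = NA_real_, oc_year = NA_integer_, oc_stage = NA_integer_,
    oc_hist = NA_character_, referred_year = NA_integer_,
    panel_tested = FALSE, panel_year = NA_integer_, pred_tested = FALSE,
    pred_year = NA_integer_, result_pos = FALSE, pos_year = NA_integer_,
    brrm_age = NA_real_, crrm_age = NA_real_, rrso_age = NA_real_,
    pop_start = Inf, n_screens = 0L, pathway = 0L, born = TRUE,
    cascade_at_risk = FALSE, ...)
}

test_that("cohort selection applies the age cut-off and prior-variant rule", {
  p1 <- base_person(1L, 1L, "proband")
  p1$bc1_age <- 50; p1$bc1_year <- 30L
  p2 <- base_person(2L, 2L, "proband")        # diagnosed at 82: excluded
  p2$bc1_age <- 82; p2$bc1_year <- 62L
  p3 <- base_person(3L, 3L, "proband")        # variant known before cancer
  p3$bc1_age <- 50; p3$bc1_year <- 30L
  p3$result_pos <- TRUE; p3$pos_year <- 10L; p3$pred_tested <- TRUE
  p4 <- base_person(4L, 1L, "mother")
  po <- dplyr::bind_rows(p1, p2, p3, p4)
  co <- select_cohort(fake_sim(po))
  expect_identical(co$probands$id, 1L)
  expect_identical(co$relatives$id, 4L)
  expect_identical(co$relatives$anchor_year, 30L)
  # empty log yields an empty cohort
  co0 <- select_cohort(fake_sim(base_person(1L, 1L, "proband")))
  expect_identical(nrow(co0$probands), 0L)
})

test_that("detection rate counts identified carriers by mechanism", {
  rows <- lapply(1:4, function(i) base_person(i, i, "mother"))
  po <- dplyr::bind_rows(rows)
  po$gene <- c(1L, 1L, 1L, 0L)
  po$result_pos <- c(TRUE, TRUE, FALSE, FALSE)
  po$pred_tested <- c(TRUE, FALSE, FALSE, FALSE)
  po$pred_year <- c(12L, NA, NA, NA)
  po$pos_year <- c(12L, 20L, NA, NA)
  po$panel_tested <- c(FALSE, TRUE, FALSE, FALSE)
  dr <- detection_rate(po)
  expect_identical(dr$n_carriers, 3L)
  expect_identical(dr$n_identified, 2L)
  expect_equal(dr$rate, 2 / 3)
  expect_identical(dr$n_predictive, 1L)
  expect_identical(dr$n_diagnostic, 1L)
  expect_equal(detection_rate(po, gene = "BRCA2")$n_carriers, 0L)
})

test_that("life metrics reproduce the toy arithmetic", {
  po <- dplyr::bind_rows(base_person(1L, 1L, "mother"),
                         base_person(2L, 2L, "mother"))
  po$death_age <- c(80, 90)
  lm <- life_metrics(po, anchor_year = c(30, 30))  # anchor age 50 for both
  expect_equal(lm$life_expectancy, 85)
  expect_equal(lm$anchored_life_years, 35)
  expect_lt(lm$le_lo, 85); expect_gt(lm$le_hi, 85)
  # anchor at the death year gives zero anchored years for that person
  lm2 <- life_metrics(po[1, ], anchor_year = 60)
  expect_equal(lm2$anchored_life_years, 0)
  po$death_age[1] <- NA
  expect_error(life_metrics(po, anchor_year = c(30, 30)), "terminal")
})

test_that("cumulative incidence matches the survfit product-limit oracle", {
  set.seed(31)
  n <- 300
  ev <- sample(c(1:20, NA), n, replace = TRUE)
  cens <- sample(1:25, n, replace = TRUE)
  rel <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    r <- base_person(i, i, "mother")
    r$anchor_year <- 0L
    r$bc1_year <- if (is.na(ev[i])) NA_integer_ else as.integer(ev[i])
    r$death_year <- as.integer(cens[i])
    r
  }))
  curves <- incidence_and_uptake_curves(rel, t_max = 25)
  km <- curves[curves$outcome == "breast", ]
  time_obs <- pmin(ifelse(is.na(ev), Inf, ev), cens)
  status <- !is.na(ev) & ev <= cens
  sf <- survival::survfit(survival::Surv(time_obs, status) ~ 1)
  sf_at <- stats::stepfun(sf$time, c(1, sf$surv))
  expect_equal(km$cum_inc, 1 - sf_at(km$time), tolerance = 1e-10)
  # degenerate cases: no events, and all events in year one
  rel0 <- rel; rel0$bc1_year <- NA_integer_
  c0 <- incidence_and_uptake_curves(rel0, t_max = 10)
  expect_true(all(c0$cum_inc[c0$outcome == "breast"] == 0))
  rel1 <- rel; rel1$bc1_year <- 1L; rel1$death_year <- 40L
  c1 <- incidence_and_uptake_curves(rel1, t_max = 5)
  ci <- c1[c1$outcome == "breast", ]
  expect_equal(ci$cum_inc[ci$time >= 1], rep(1, sum(ci$time >= 1)))
})

test_that("summary report renders consistent counts and zero test rows", {
  pop <- generate_carrier_population(120, the_params, seed = 91)
  s1 <- run_simulation(pop, build_scenario("no_testing", seed = 91),
                       the_params)
  s2 <- run_simulation(pop, build_scenario("current_practice", seed = 91),
                       the_params)
  rep_ <- summary_report(list(none = s1, current = s2))
  val <- function(scn, out, grp = "probands") {
    rep_$value[rep_$scenario == scn & rep_$outcome == out & rep_$group == grp]
  }
  expect_identical(val("none", "diagnostic_tests"), 0)
  expect_identical(val("none", "predictive_tests"), 0)
  expect_gt(val("current", "diagnostic_tests"), 0)
  # percentage labels recompute from the counts
  lab <- rep_$label[rep_$scenario == "current" & rep_$group == "probands" &
                      rep_$outcome == "diagnostic_tests"]
  n_pro <- val("current", "total")
  n_diag <- val("current", "diagnostic_tests")
  expect_match(lab, sprintf("%.2f%%", 100 * n_diag / n_pro), fixed = TRUE)
  # autoplot returns a ggplot object for the curves
  co <- select_cohort(s1)
  rel <- co$relatives[co$relatives$alive_at_anchor, ]
  pl <- ggplot2::autoplot(incidence_and_uptake_curves(rel))
  expect_s3_class(pl, "ggplot")
  # writer emits csv + markdown
  base <- withr::local_tempfile()
  write_outcomes(rep_, base)
  expect_true(file.exists(paste0(base, ".csv")))
  expect_true(file.exists(paste0(base, ".md")))
})
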