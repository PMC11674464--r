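test_that("scenario configurations encode the four testing policies", {
  s1 <- build_scenario("no_testing")
  s3 <- build_scenario("optimised_referral")
  expect_identical(s1$scenario, "no_testing")
  expect_identical(s3$panel, "high_risk")
  expect_error(build_scenario("screen_everyone"), "unknown scenario")
  expect_error(build_scenario("no_testing", horizon = 0), "horizon")
  expect_error(build_scenario("no_testing", horizon = 200), "horizon")
})

test_that("runs are deterministic and the no-testing scenario is test-free", {
  pop <- generate_population(60, the_params, seed = 41)
  sc <- build_scenario("no_testing", seed = 41)
  a <- run_simulation(pop, sc, the_params)
  b <- run_simulation(pop, sc, the_params)
  expect_identical(a$population, b$population)
  expect_identical(sum(a$population$panel_tested), 0L)
  expect_identical(sum(a$population$pred_tested), 0L)
  # no risk-reducing surgery without a known variant (CRRM after cancer may
  # still occur)
  expect_identical(sum(!is.na(a$population$brrm_age)), 0L)
  expect_identical(sum(!is.na(a$population$rrso_age)), 0L)
  ev <- tidy(a)
  expect_false(any(ev$event %in% c("diagnostic_test", "predictive_test")))
})

test_that("a static population never activates unborn members", {
  pop <- generate_population(80, the_params, proband_age_group = c(20, 24),
                             seed = 19)
  expect_gt(sum(pop$alive0 == "unborn"), 0)
  sc_static <- build_scenario("no_testing", dynamic_population = FALSE,
                              seed = 19)
  sim <- run_simulation(pop, sc_static, the_params)
  unb <- sim$population[pop$alive0 == "unborn", ]
  expect_true(all(!unb$born))
  expect_true(all(is.na(unb$bc1_age)))
  sc_dyn <- build_scenario("no_testing", dynamic_population = TRUE, seed = 19)
  sim2 <- run_simulation(pop, sc_dyn, the_params)
  expect_gt(sum(sim2$population[pop$alive0 == "unborn", ]$born), 0)
})

test_that("a one-year horizon runs exactly one cycle", {
  pop <- generate_population(40, the_params, seed = 77)
  sc <- build_scenario("no_testing", horizon = 1L, seed = 77)
  sim <- run_simulation(pop, sc, the_params)
  ev <- tidy(sim)
  expect_true(all(ev$year <= 1))
})

test_that("per-person event years are non-decreasing and death is terminal", {
  pop <- generate_population(120, the_params, seed = 55)
  sim <- run_simulation(pop, build_scenario("current_practice", seed = 55),
                        the_params)
  ev <- tidy(sim)
  by_person <- split(ev, ev$id)
  bad <- vapply(by_person, function(d) {
    term <- d$event %in% c("death", "exit")
    any(diff(d$year) < 0) || (any(term) && any(which(term) < nrow(d)))
  }, logical(1))
  expect_false(any(bad))
  # conservation: every born member ends dead or exited
  po <- sim$population
  fin <- po[po$born & po$member, ]
  expect_true(all(!fin$alive))
  expect_true(all(!is.na(fin$death_cause)))
})

test_that("zero uptake collapses scenarios 2-4 onto scenario 1 exactly", {
  pop <- generate_population(150, the_params, seed = 61)
  s1 <- run_simulation(pop, build_scenario("no_testing", seed = 61),
                       the_params)
  cols <- c("bc1_age", "bc2_age", "oc_age", "death_age", "death_cause",
            "brrm_age", "crrm_age", "rrso_age", "n_screens")
  for (nm in c("current_practice", "optimised_referral", "test_all_breast")) {
    sz <- run_simulation(pop, build_scenario(nm, seed = 61,
                                             uptake_multiplier = 0),
                         the_params)
    expect_identical(sz$population[cols], s1$population[cols], label = nm)
    expect_identical(sum(sz$population$panel_tested), 0L)
  }
})

test_that("diagnostically tested probands nest across scenarios 2-4", {
  pop <- generate_population(400, the_params, seed = 21)
  run <- function(nm) run_simulation(pop, build_scenario(nm, seed = 21),
                                     the_params)
  s2 <- run("current_practice"); s3 <- run("optimised_referral")
  s4 <- run("test_all_breast")
  pro <- pop$rel == "proband"
  t2 <- s2$population$panel_tested[pro]
  t3 <- s3$population$panel_tested[pro]
  t4 <- s4$population$panel_tested[pro]
  expect_true(all(t3[t2]))
  expect_true(all(t4[t3]))
  expect_gt(sum(t3), sum(t2))
  expect_gt(sum(t4), sum(t3))
})

test_that("sensitivity toggles alter who can be tested and when", {
  toy <- make_toy_population("one_carrier_family", n_families = 30, seed = 9)
  sc <- build_scenario("optimised_referral", seed = 9,
                       disable_relative_diagnostic_testing = TRUE,
                       force_full_predictive_uptake = TRUE)
  sim <- run_simulation(toy$population, sc, toy$params)
  po <- sim$population
  expect_identical(sum(po$panel_tested & po$rel != "proband"), 0L)
  # everyone eligible at identification cascades in that year; only
  # relatives born after it may test later
  idf <- which(sim$fam_gene > 0)
  for (f in idf) {
    members <- po[po$fam == f & po$member & po$pred_tested, ]
    late <- members$age_entry + sim$fam_year[f] < 0
    expect_true(all(members$pred_year[!late] == sim$fam_year[f]))
  }
  expect_gt(sum(po$pred_tested), 0)
})

test_that("the carrier-family fixture identifies the variant in the diagnosis year", {
  toy <- make_toy_population("one_carrier_family", n_families = 10, seed = 9)
  sim <- run_simulation(toy$population, toy$scenario, toy$params)
  po <- sim$population
  pro <- po[po$rel == "proband", ]
  dxd <- which(!is.na(pro$bc1_year))
  expect_gt(length(dxd), 5)
  for (i in dxd) {
    f <- pro$fam[i]
    expect_identical(sim$fam_gene[f], match("BRCA1", hboc_genes()))
    expect_identical(sim$fam_year[f], pro$bc1_year[i])
    expect_identical(floor(pro$bc1_age[i]), 47)
  }
})

test_that("screen detection increases with surveillance intensity", {
  pop <- generate_carrier_population(250, the_params, seed = 33)
  run <- function(nm) run_simulation(pop, build_scenario(nm, seed = 33),
                                     the_params)
  s1 <- run("no_testing"); s4 <- run("test_all_breast")
  screens1 <- sum(s1$population$n_screens)
  screens4 <- sum(s4$population$n_screens)
  expect_gt(screens4, screens1)
  sd1 <- sum(s1$population$bc1_mode == "screen", na.rm = TRUE)
  sd4 <- sum(s4$population$bc1_mode == "screen", na.rm = TRUE)
  expect_gte(sd4, sd1)
})
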