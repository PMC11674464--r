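test_that("referral probabilities follow the odds model arithmetic", {
  # triple-negative reference: constant only
  expect_equal(referral_probability("breast", 35, FALSE, "TN", p = the_params),
               3.23 / 4.23, tolerance = 1e-12)
  # breast, 40-49, high grade, TN, survival >= 12 months
  odds <- 3.23 * 0.38 * 2.37
  expect_equal(referral_probability("breast", 45, TRUE, "TN", p = the_params),
               odds / (1 + odds), tolerance = 1e-12)
  # ovarian, 60-74, high grade, serous, no prior breast cancer
  odds_o <- 3.09 * 0.20 * 1.06
  expect_equal(referral_probability("ovary", 65, TRUE, histology = "serous",
                                    p = the_params),
               odds_o / (1 + odds_o), tolerance = 1e-12)
  # prior breast cancer multiplies the ovarian odds by 17.75
  with_prior <- referral_probability("ovary", 65, TRUE, histology = "serous",
                                     prior_breast = TRUE, p = the_params)
  expect_equal(with_prior / (1 - with_prior) / (odds_o / 1), 17.75,
               tolerance = 1e-9)
  expect_error(referral_probability("breast", 45, TRUE, "lobular",
                                    p = the_params), "subtype")
  expect_error(referral_probability("ovary", 45, TRUE, histology = "sarcoma",
                                    p = the_params), "histology")
})

test_that("testing eligibility implements the five funded criteria", {
  # TN at 48, no family history
  expect_true(is_test_eligible("breast", 48, subtype = "TN"))
  # TN at 62 needs an affected relative
  expect_false(is_test_eligible("breast", 62, subtype = "TN"))
  expect_true(is_test_eligible("breast", 62, subtype = "TN", n_affected = 1))
  # strong family history qualifies any subtype
  expect_true(is_test_eligible("breast", 60, subtype = "HRplus",
                               n_affected = 3))
  expect_false(is_test_eligible("breast", 60, subtype = "HRplus",
                                n_affected = 2))
  # bilateral breast cancer
  expect_true(is_test_eligible("breast", 70, subtype = "HRplus",
                               bilateral = TRUE))
  # serous grade 2/3 at any age; non-mucinous grade 2/3 under 70
  expect_true(is_test_eligible("ovary", 75, grade = 3, histology = "serous"))
  expect_true(is_test_eligible("ovary", 65, grade = 2,
                               histology = "endometrioid"))
  expect_false(is_test_eligible("ovary", 75, grade = 1, histology = "mucinous"))
  expect_false(is_test_eligible("ovary", 72, grade = 3,
                                histology = "endometrioid"))
})

test_that("predictive uptake lookup applies bands and the male rate ratio", {
  expect_identical(
    predictive_uptake_probability(1, 35, TRUE, 0, the_params), 0.286)
  expect_equal(
    predictive_uptake_probability(2, 25, FALSE, 4, the_params), 0.034 * 0.422)
  expect_identical(
    predictive_uptake_probability(1, 17, TRUE, 0, the_params), 0)
  expect_identical(
    predictive_uptake_probability(1, 62, TRUE, 2, the_params), 0.014)
  # degrees beyond the second use the second-degree rates
  expect_identical(
    predictive_uptake_probability(3, 35, TRUE, 0, the_params), 0.112)
})

test_that("the assay is perfect and panel membership decides detection", {
  chek2 <- match("CHEK2_1100delC", hboc_genes())
  brca2 <- match("BRCA2", hboc_genes())
  expect_identical(test_result(chek2, "diagnostic", "high_risk"), "negative")
  expect_identical(test_result(chek2, "diagnostic", "extended"), "positive")
  expect_identical(test_result(brca2, "predictive", family_gene = brca2),
                   "positive")
  expect_identical(test_result(0L, "diagnostic", "extended"), "negative")
  expect_identical(test_result(brca2, "predictive", family_gene = chek2),
                   "negative")
})

three_gen <- function() {
  # ids: 1-2 maternal gps, 3-4 paternal gps, 5 mother, 6 father, 7 proband,
  # 8 sibling, 9 pibling (maternal aunt), 10 nibling (sibling's child via
  # out-of-table co-parent)
  tibble::tibble(
    id = 1:10,
    mother = c(NA, NA, NA, NA, 1L, 3L, 5L, 5L, 1L, 8L),
    father = c(NA, NA, NA, NA, 2L, 4L, 6L, 6L, 2L, NA))
}

test_that("a positive maternal grandfather excludes the paternal side", {
  fam <- three_gen()
  poss <- carrier_possible(fam, positive_ids = 2L)
  names(poss) <- fam$id
  expect_false(poss[["3"]]); expect_false(poss[["4"]]); expect_false(poss[["6"]])
  expect_true(poss[["5"]]); expect_true(poss[["7"]]); expect_true(poss[["9"]])
  expect_true(poss[["10"]])  # nibling reachable through the maternal line
})

test_that("a child of two tested-negative parents is an obligate non-carrier", {
  fam <- three_gen()
  poss <- carrier_possible(fam, positive_ids = 9L, negative_ids = c(5L, 6L))
  names(poss) <- fam$id
  expect_false(poss[["7"]]); expect_false(poss[["8"]]); expect_false(poss[["10"]])
  expect_true(poss[["1"]] || poss[["2"]])
  ok <- predictive_eligible(fam, positive_ids = 9L, negative_ids = c(5L, 6L))
  expect_false(ok[7]); expect_false(ok[5])  # obligate and already-tested
})

test_that("eligibility matches the exhaustive enumeration oracle", {
  set.seed(99)
  n_checked <- 0L
  for (s in 1:8) {
    fam <- random_small_pedigree(700 + s, max_members = 9)
    ft <- fam[, c("id", "mother", "father")]
    members <- ft$id
    # exhaustive over result sets of up to two members, plus a batch of
    # random three-member result sets
    combos <- c(lapply(members, function(a) a),
                utils::combn(members, 2, simplify = FALSE),
                replicate(10, sample(members, 3), simplify = FALSE))
    for (who in combos) {
      for (draw in seq_len(2^length(who))) {
        is_pos <- as.logical(bitwAnd(draw - 1L, 2^(seq_along(who) - 1L)))
        pos <- who[is_pos]; neg <- who[!is_pos]
        if (!length(pos)) next  # knowledge requires at least one positive
        oracle <- enumerate_genotype_constraints(ft, pos, neg)
        fast <- carrier_possible(ft, pos, neg)
        expect_identical(unname(fast), unname(oracle$possible),
                         info = paste("seed", s, "pos", paste(pos, collapse = ","),
                                      "neg", paste(neg, collapse = ",")))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 500)
})

test_that("relative pair construction identifies first/second degree kin", {
  pop <- generate_population(20, the_params, seed = 13,
                             baseline_history = FALSE)
  pairs <- hbocsim:::build_relative_pairs(pop)
  deg_of <- function(i, j) {
    a <- pairs$ptr[i] + 1L; b <- pairs$ptr[i + 1L]
    if (b < a) return(NA_integer_)
    hit <- which(pairs$jj[a:b] == j)
    if (!length(hit)) NA_integer_ else pairs$dd[a:b][hit]
  }
  pro <- which(pop$rel == "proband")[1]
  f <- pop$fam[pro]
  rows <- which(pop$fam == f)
  rel <- setNames(pop$rel[rows], rows)
  for (r in rows) {
    if (r == pro || !pop$member[r]) next
    expected <- switch(pop$rel[r],
      mother = 1L, father = 1L, sibling = 1L, child = 1L,
      grandmother = 2L, grandfather = 2L, pibling = 2L, nibling = 2L,
      grandchild = 2L, NA_integer_)
    expect_identical(deg_of(pro, r), expected, info = pop$rel[r])
    expect_identical(deg_of(r, pro), expected, info = paste("rev", pop$rel[r]))
  }
})
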