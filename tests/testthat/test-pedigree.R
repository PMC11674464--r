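test_that("degenerate parity collapses families to the forced minimum", {
  toy <- make_toy_population("minimal", n_families = 5, seed = 3)
  expect_true(all(family_sizes(toy$population)$size == 7L))
  expect_setequal(unique(toy$population$rel[toy$population$member]),
                  c("proband", "mother", "father", "grandmother", "grandfather"))
})

test_that("generation is deterministic given the seed", {
  a <- generate_population(30, the_params, seed = 99)
  b <- generate_population(30, the_params, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_population(30, the_params, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("sample_parity inverts the age-group CDF", {
  p <- the_params
  p$parity_age <- tibble::tibble(
    age_group = rep(c("0-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45+"),
                    each = 3),
    children = rep(0:2, 7),
    cdf = rep(c(0.3, 0.3, 1), 7))
  expect_identical(sample_parity(30, p, u = 0.5), 2L)
  expect_identical(sample_parity(30, p, u = 0.29), 0L)
  expect_identical(sample_parity(30, p, u = 0.31), 2L)  # flat segment skips 1
  p$parity_age$cdf <- rep(c(1, 1, 1), 7)
  expect_identical(sample_parity(c(20, 50, 80), p, u = c(0.1, 0.5, 0.99)),
                   c(0L, 0L, 0L))
})

test_that("empirical parity frequencies match the CDF", {
  n <- 20000
  set.seed(1)
  draws <- sample_parity(rep(52, n), the_params)
  cdf_tab <- the_params$parity_age
  cdf <- cdf_tab$cdf[cdf_tab$age_group == "45+"]
  emp <- cumsum(tabulate(draws + 1L, nbins = 9)) / n
  # binomial error on each CDF point
  expect_true(all(abs(emp - cdf) < 3 * sqrt(cdf * (1 - cdf) / n) + 1e-9))
})

test_that("Mendelian transmission from a single carrier parent is one half", {
  n <- 20000
  trios <- build_trios(n)
  p <- with_prevalence(the_params, 0.3)
  g <- assign_genotypes(trios, p, seed = 8)
  dad <- g$gene[g$rel == "father"]; mom <- g$gene[g$rel == "mother"]
  kid <- g$gene[g$rel == "child"]
  one <- xor(dad > 0, mom > 0)
  freq <- mean(kid[one] > 0)
  se <- sqrt(0.25 / sum(one))
  expect_lt(abs(freq - 0.5), 4 * se)
  # no de novo: child of two non-carriers is always a non-carrier
  expect_true(all(kid[dad == 0 & mom == 0] == 0))
})

test_that("polygenic scores preserve unit variance under the midparent model", {
  n <- 20000
  trios <- build_trios(n)
  g <- assign_genotypes(trios, the_params, seed = 12)
  zb_kid <- g$zb[g$rel == "child"]
  zb_mid <- (g$zb[g$rel == "father"] + g$zb[g$rel == "mother"]) / 2
  expect_lt(abs(var(zb_kid) - 1), 0.03)
  expect_lt(abs(var(zb_kid - zb_mid) - 0.5), 0.02)
  expect_lt(abs(mean(zb_kid)), 0.02)
})

test_that("sex assignment is balanced outside the forced relations", {
  pop <- generate_population(400, the_params, seed = 31)
  free <- pop$rel %in% c("sibling", "child", "nibling", "grandchild", "pibling")
  expect_lt(abs(mean(pop$female[free]) - 0.5), 0.02)
  expect_true(all(pop$female[pop$rel %in% c("mother", "grandmother", "proband")]))
  expect_true(all(!pop$female[pop$rel %in% c("father", "grandfather")]))
})

test_that("family structure obeys the two-parents/four-grandparents rule", {
  pop <- generate_population(50, the_params, seed = 17)
  per_fam <- table(pop$fam[pop$rel %in% c("mother", "father")])
  expect_true(all(per_fam == 2))
  gp <- table(pop$fam[pop$rel %in% c("grandmother", "grandfather")])
  expect_true(all(gp == 4))
  # acyclic with parents preceding children in id order
  kid <- which(!is.na(pop$mother))
  expect_true(all(pop$mother[kid] < pop$id[kid]))
  expect_true(all(pop$father[kid] < pop$id[kid]))
})

test_that("family size under deterministic parity matches the closed form", {
  p <- the_params
  # everyone completes exactly 2 children (CDF 0 below 2)
  p$parity_completed$cdf <- c(0, 0, rep(1, 7))
  p$parity_age <- derive_parity_age(p$parity_completed, p$maternal_age)
  pop <- generate_population(40, p, proband_age_group = c(50, 54), seed = 4,
                             baseline_history = FALSE)
  # closed form: 7 forced + 1 sibling + 2 piblings + 2 children + 2 niblings
  # + 4 grandchildren = 18 generated members per family
  members <- pop[pop$member, ]
  expect_true(all(table(members$fam) == 18))
})

test_that("carrier-conditioned generation forces a consistent lineage", {
  pop <- generate_population(200, the_params, seed = 6,
                             proband_gene = "BRCA2",
                             baseline_history = FALSE)
  pro <- pop[pop$rel == "proband", ]
  expect_true(all(pro$gene == match("BRCA2", hboc_genes())))
  # one parent of each proband carries the same variant
  gidx <- match("BRCA2", hboc_genes())
  expect_true(all(pop$gene[pro$mother] == gidx | pop$gene[pro$father] == gidx))
})

test_that("PED export/import round-trips a population", {
  pop <- generate_population(5, the_params, seed = 23)
  path <- withr::local_tempfile(fileext = ".ped")
  export_pedigree(pop, path)
  back <- import_pedigree(path)
  expect_identical(nrow(back), nrow(pop))
  for (col in c("id", "fam", "rel", "female", "member", "mother", "father",
                "gene", "alive0", "bc1_age0")) {
    expect_equal(back[[col]], pop[[col]], info = col)
  }
  # minimal family exports exactly 7 rows
  toy <- make_toy_population("minimal", n_families = 1, seed = 2)
  path2 <- withr::local_tempfile(fileext = ".ped")
  export_pedigree(toy$population, path2)
  expect_identical(length(readLines(path2)), 7L)
})

test_that("a person recorded twice is rejected on import", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("1 1 0 0 1 1", "1 2 0 0 2 1", "1 3 1 2 2 1", "1 3 2 1 2 1"),
             path)
  jsonlite::write_json(list(columns = list()), paste0(path, ".json"))
  expect_error(import_pedigree(path), "more than once")
  writeLines(c("1 1 0 0 1", "1 2 0 0 2 1"), path)
  expect_error(import_pedigree(path), "line 1")
})
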