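# Deterministic toy populations and the brute-force oracle for the
# obligate-non-carrier / lineage-localisation logic.

#' Exhaustively enumerate Mendelian-consistent carrier sets
#'
#' Independent oracle for [carrier_possible()]: enumerates every subset of
#' family members that could jointly carry a single family variant - the
#' subset must contain every observed positive, no observed negative, and
#' have exactly one origin (a member with no carrier parent in the subset,
#' who must be a founder or have a parent outside the table); every other
#' carrier must have a carrier parent. A person is an obligate non-carrier
#' iff no consistent subset contains them.
#'
#' @param fam_tbl Tibble with `id`, `mother`, `father` (NA for founders);
#'   at most 16 members.
#' @param positive_ids,negative_ids Observed results.
#' @return List: `assignments` (list of id vectors), `possible` (logical per
#'   row), `consistent` (FALSE when the observations admit no assignment,
#'   e.g. a positive child of two negative parents).
#' @export
enumerate_genotype_constraints <- function(fam_tbl, positive_ids,
                                           negative_ids = integer()) {
  n <- nrow(fam_tbl)
  if (n > 16) abort("enumeration oracle limited to 16 members")
  loc <- function(ids) match(ids, fam_tbl$id)
  m <- loc(fam_tbl$mother); f <- loc(fam_tbl$father)
  # founder-capable: can introduce the variant from outside the table
  capable <- (is.na(fam_tbl$mother) | is.na(m)) |
    (is.na(fam_tbl$father) | is.na(f))
  pos <- loc(positive_ids); pos <- pos[!is.na(pos)]
  neg <- loc(negative_ids); neg <- neg[!is.na(neg)]

  # all non-empty subsets as a logical matrix, filtered vectorised
  masks <- seq_len(2^n - 1L)
  M <- outer(masks, 0:(n - 1L), function(a, b) bitwAnd(a, 2^b) > 0)
  ok <- rep(TRUE, length(masks))
  if (length(pos)) ok <- ok & rowSums(M[, pos, drop = FALSE]) == length(pos)
  if (length(neg)) ok <- ok & rowSums(M[, neg, drop = FALSE]) == 0
  par_in <- matrix(FALSE, length(masks), n)
  for (r in seq_len(n)) {
    if (!is.na(m[r])) par_in[, r] <- par_in[, r] | M[, m[r]]
    if (!is.na(f[r])) par_in[, r] <- par_in[, r] | M[, f[r]]
  }
  orig <- M & !par_in
  ok <- ok & rowSums(orig) == 1L
  if (any(ok)) {
    ocol <- max.col(orig[ok, , drop = FALSE], ties.method = "first")
    ok[ok] <- capable[ocol]
  }
  keep <- which(ok)
  assignments <- lapply(keep, function(i) fam_tbl$id[M[i, ]])
  possible <- if (length(keep)) {
    colSums(M[keep, , drop = FALSE]) > 0
  } else rep(FALSE, n)
  consistent <- if (length(pos)) length(assignments) > 0 else TRUE
  list(assignments = assignments, possible = possible,
       consistent = consistent)
}

#' Named deterministic toy populations
#'
#' Miniature fixtures with analytically known outcomes:
#' \describe{
#'   \item{`minimal`}{Parity degenerate at zero children: each family is
#'     exactly proband + 2 parents + 4 grandparents.}
#'   \item{`no_cancer_world`}{All cancer hazards zero: no diagnoses ever,
#'     in any scenario.}
#'   \item{`certain_cancer_proband`}{A hazard spike forces breast-cancer
#'     onset at age 45 with a degenerate 2-year sojourn: the proband is
#'     diagnosed at 47 (absent screening).}
#'   \item{`one_carrier_family`}{`certain_cancer_proband` with a forced
#'     BRCA1-carrier proband, referral and uptake forced to 1
#'     (optimised-referral scenario): the family variant is identified in
#'     the diagnosis year.}
#' }
#'
#' @param name Fixture name.
#' @param n_families Number of families (default 3).
#' @param seed Integer seed.
#' @return List: `population`, `params`, `scenario`, and `expected` (named
#'   list of facts the fixture guarantees).
#' @export
make_toy_population <- function(name, n_families = 3L, seed = 42L) {
  p0 <- default_parameters()
  fixtures <- c("minimal", "no_cancer_world", "certain_cancer_proband",
                "one_carrier_family")
  if (!name %in% fixtures) {
    abort(paste0("unknown fixture '", name, "'; expected one of: ",
                 paste(fixtures, collapse = ", ")))
  }
  zero_hazards <- function(p) {
    p$baseline_incidence$hazard <- 0
    p$penetrance$hazard <- 0
    p
  }
  spike_at_45 <- function(p) {
    p <- zero_hazards(p)
    p$baseline_incidence$hazard[p$baseline_incidence$organ == "breast" &
                                  p$baseline_incidence$age == 45] <- 50
    p$penetrance$hazard[p$penetrance$organ == "breast" &
                          p$penetrance$age == 45] <- 50
    p$sojourn$meanlog <- log(2)
    p$sojourn$sdlog <- 0
    p$constants$never_screen <- 1   # symptomatic detection only
    p
  }
  no_deaths_before_60 <- function(p) {
    p$lifetable$qx[p$lifetable$age < 60] <- 0
    p
  }
  switch(name,
    minimal = {
      p <- p0
      p$parity_completed$cdf <- rep(1, nrow(p$parity_completed))
      p$parity_age <- derive_parity_age(p$parity_completed, p$maternal_age)
      pop <- generate_population(n_families, p = p, seed = seed,
                                 proband_age_group = c(30, 34))
      list(population = pop, params = p,
           scenario = build_scenario("no_testing", seed = seed),
           expected = list(family_size = 7L))
    },
    no_cancer_world = {
      p <- zero_hazards(p0)
      pop <- generate_population(n_families, p = p, seed = seed)
      list(population = pop, params = p,
           scenario = build_scenario("current_practice", seed = seed),
           expected = list(n_diagnoses = 0L))
    },
    certain_cancer_proband = {
      p <- no_deaths_before_60(spike_at_45(p0))
      pop <- generate_population(n_families, p = p, seed = seed,
                                 proband_age_group = c(30, 34))
      list(population = pop, params = p,
           scenario = build_scenario("no_testing", seed = seed),
           expected = list(proband_onset_age = 45, proband_dx_age = 47))
    },
    one_carrier_family = {
      p <- no_deaths_before_60(spike_at_45(p0))
      p$testing_uptake$uptake <- c(1, 1)
      # triple-negative BRCA1 tumours guarantee testing eligibility at 47
      bs <- p$breast_subtype
      p$breast_subtype$prob[bs$gene == "BRCA1"] <-
        ifelse(bs$subtype[bs$gene == "BRCA1"] == "TN", 1, 0)
      pop <- generate_population(n_families, p = p, seed = seed,
                                 proband_age_group = c(30, 34),
                                 proband_gene = "BRCA1")
      list(population = pop, params = p,
           scenario = build_scenario("optimised_referral", seed = seed),
           expected = list(variant_identified_in_dx_year = TRUE))
    })
}
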