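# Breast screening and risk-reducing surgery: population (BreastScreen-style)
# participation, moderate/high-risk surveillance, screen detection, and
# surgery uptake/effect.

#' Sample the age at first screen for a pathway
#'
#' Population pathway: with probability `never_screen` (~30%) the woman
#' never participates; otherwise the starting age is drawn from the
#' participation-start distribution (ages 40-64). High-risk pathway: the
#' first surveillance screen happens at the later of the window opening and
#' the current age, plus an adherence delay. Moderate-risk mammography uses
#' the high-risk start distribution delayed by ten further years.
#'
#' @param person One or more `hboc_population` rows (needs `id`, `female`;
#'   `age_entry` or `age` used as the current age for risk pathways).
#' @param pathway `"population"`, `"high_risk"` or `"moderate_risk"`.
#' @param p An `hboc_params` object.
#' @param seed Integer seed.
#' @param year Draw-stream year (defaults to 0; supply the cycle for in-run
#'   draws).
#' @return Numeric vector of starting ages; `Inf` means never.
#' @export
sample_screening_start <- function(person, pathway = "population",
                                   p = default_parameters(), seed = 1L,
                                   year = 0L) {
  stopifnot(pathway %in% c("population", "high_risk", "moderate_risk"))
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  n <- nrow(person)
  u <- cr_unif(seed, person$id, PROC$screen_start, year)
  if (pathway == "population") {
    nv <- pp$const$never_screen
    out <- rep(Inf, n)
    starters <- u >= nv
    u2 <- (u[starters] - nv) / (1 - nv)
    out[starters] <- draw_cat(u2, pp$start_cdf, pp$start_age)
    return(out)
  }
  age <- col_or(person, "age", col_or(person, "age_entry", 0))
  ud <- cr_unif(seed, person$id, PROC$hr_start, year)
  delay <- draw_cat(ud, pp$delay_hr_start$cdf, pp$delay_hr_start$years)
  if (pathway == "high_risk") {
    pmax(pp$const$hr_mammo_lo, age) + delay
  } else {
    pmax(pp$const$hr_mammo_lo, age) + delay + pp$const$moderate_start_delay
  }
}

#' Outcome of one screening attendance
#'
#' If a preclinical tumour is present it is detected with the combined
#' sensitivity of the attended modalities (`1 - prod(1 - sens)`); otherwise
#' the result is a false positive with `1 - prod(spec)`.
#'
#' @param has_preclinical Logical: is screen-detectable disease present?
#' @param modalities Character vector subset of
#'   `c("mammography", "mri")` (same set applied to all persons).
#' @param age Attained ages (vectorised with `has_preclinical`).
#' @param p An `hboc_params` object.
#' @param u Uniform draws in (0,1), one per person (injectable); defaults to
#'   `runif`.
#' @return Character vector in `c("true_positive", "false_positive",
#'   "true_negative", "false_negative")`.
#' @export
screen_event <- function(has_preclinical, modalities, age,
                         p = default_parameters(), u = NULL) {
  stopifnot(all(modalities %in% c("mammography", "mri")), length(modalities) >= 1)
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  n <- length(has_preclinical)
  age <- rep_len(age, n)
  if (is.null(u)) u <- runif(n)
  ai <- pmin(floor(age), 100) + 1L
  sens <- rep(0, n); spec <- rep(1, n)
  if ("mammography" %in% modalities) {
    sens <- 1 - (1 - sens) * (1 - pp$mam_sens[ai])
    spec <- spec * pp$mam_spec[ai]
  }
  if ("mri" %in% modalities) {
    sens <- 1 - (1 - sens) * (1 - pp$mri_sens[ai])
    spec <- spec * pp$mri_spec[ai]
  }
  ifelse(has_preclinical,
         ifelse(u < sens, "true_positive", "false_negative"),
         ifelse(u < 1 - spec, "false_positive", "true_negative"))
}

#' Risk pathway implied by a positive genetic test
#'
#' High-risk genes (BRCA1, BRCA2, PALB2) put a woman on the high-risk
#' surveillance pathway (annual mammography 25-64 plus annual MRI 25-59);
#' the extended-panel genes imply the moderate-risk pathway (annual
#' mammography 35-59). A negative or absent result leaves the population
#' pathway unchanged.
#'
#' @param gene Gene index (1-8 into [hboc_genes()]) or gene name; 0/NA or a
#'   negative result maps to `"population"`.
#' @param result Optional result vector (`"positive"`/`"negative"`).
#' @return Character pathway per person.
#' @export
update_risk_pathway <- function(gene, result = "positive") {
  if (is.character(gene)) gene <- match(gene, GENES)
  k <- max(length(gene), length(result))
  gene <- rep_len(gene, k); result <- rep_len(result, k)
  ifelse(result != "positive" | is.na(gene) | gene == 0L, "population",
         ifelse(GENES[pmax(gene, 1L)] %in% HIGH_RISK_GENES,
                "high_risk", "moderate_risk"))
}

#' Surgery eligibility under the gene/age rules
#'
#' BRRM and RRSO require a known high- or moderate-risk variant with a
#' non-zero uptake entry for the gene (RAD51C/D and BRIP1 carriers are
#' ineligible for BRRM; RRSO opens at 45 for RAD51C/D, 50 for PALB2, 60 for
#' BRIP1). CRRM requires a unilateral breast cancer.
#'
#' @param surgery `"BRRM"`, `"CRRM"` or `"RRSO"`.
#' @param gene Gene index or name (0/none for non-carriers).
#' @param age Current age.
#' @param known_carrier Logical: has the person a positive genetic test?
#' @param unilateral_bc Logical: exactly one breast primary (CRRM).
#' @param p An `hboc_params` object.
#' @return Logical eligibility.
#' @export
surgery_eligible <- function(surgery, gene, age, known_carrier = TRUE,
                             unilateral_bc = FALSE, p = default_parameters()) {
  stopifnot(surgery %in% c("BRRM", "CRRM", "RRSO"))
  if (is.character(gene)) gene <- match(gene, GENES)
  k <- max(length(gene), length(age))
  gene <- rep_len(gene, k); age <- rep_len(age, k)
  known_carrier <- rep_len(known_carrier, k)
  unilateral_bc <- rep_len(unilateral_bc, k)
  if (surgery == "CRRM") return(unilateral_bc)
  tab <- p$surgery_uptake[p$surgery_uptake$surgery == surgery, ]
  ok <- logical(k)
  has <- known_carrier & !is.na(gene) & gene > 0L
  if (any(has)) {
    gn <- GENES[pmax(gene, 1L)]
    ok[has] <- vapply(which(has), function(i) {
      any(tab$gene == gn[i] & tab$age_lo <= age[i] & tab$age_hi >= age[i] &
            tab$annual_prob > 0)
    }, logical(1))
  }
  ok
}

#' Sample uptake of a risk-reducing surgery
#'
#' Bernoulli draw from the age- and gene-specific annual uptake; errors for
#' an ineligible person. On uptake, the engine multiplies the organ-specific
#' hazards by the surgery's risk-reduction factor from that age onward.
#'
#' @param person One row of an `hboc_population` (needs `id`, `gene`; a
#'   `result_pos` column marks a known positive test).
#' @param surgery `"BRRM"`, `"CRRM"` or `"RRSO"`.
#' @param age Current age.
#' @param p An `hboc_params` object.
#' @param seed Integer seed.
#' @param year Draw-stream year.
#' @return Logical: surgery taken up this year.
#' @export
sample_surgery <- function(person, surgery, age, p = default_parameters(),
                           seed = 1L, year = 0L) {
  stopifnot(nrow(person) == 1)
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  ptab <- if (inherits(p, "hboc_params")) p else p$params
  rp <- col_or(person, "result_pos")
  known <- is.null(rp) || isTRUE(rp)
  bc1 <- col_or(person, "bc1_age0", NA_real_)
  bc2 <- col_or(person, "bc2_age0", NA_real_)
  uni <- !is.na(bc1) && is.na(bc2)
  if (!surgery_eligible(surgery, person$gene, age, known_carrier = known,
                        unilateral_bc = uni, p = ptab)) {
    abort(paste0("person is ineligible for ", surgery, " at age ", age))
  }
  u <- cr_unif(seed, person$id,
               switch(surgery, BRRM = PROC$brrm, RRSO = PROC$rrso,
                      CRRM = PROC$crrm), year)
  pr <- switch(surgery,
    BRRM = pp$brrm_uptake[person$gene, min(floor(age), 100) + 1L],
    RRSO = pp$rrso_uptake[person$gene, min(floor(age), 100) + 1L],
    CRRM = if (isTRUE(rp) && person$gene > 0L) pp$const$crrm_uptake_carrier
           else pp$const$crrm_uptake_noncarrier)
  u < pr
}
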