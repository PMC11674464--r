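# Clinical genetics services: referral at diagnosis, publicly funded testing
# eligibility, diagnostic (panel) and predictive (cascade) testing, and
# family-variant knowledge with lineage localisation.

#' Referral probability at cancer diagnosis
#'
#' Constant odds times the product of applicable odds-ratio terms, converted
#' to a probability `odds / (1 + odds)`. Reference categories: breast -
#' triple-negative, age under 40, low grade, survival of 12 months or more;
#' ovarian - serous/clear-cell/endometrioid histology, age under 60, low
#' grade, no prior breast cancer.
#'
#' @param organ `"breast"` or `"ovary"` (vectorised).
#' @param age Age at diagnosis.
#' @param high_grade Logical; grade 3 for breast, grade 2-3 for ovarian.
#' @param subtype Breast subtype (`"TN"`, `"HER2"`, `"HRplus"`); ignored for
#'   ovarian cancer.
#' @param histology Ovarian histology (`"serous"`, `"clear_cell"`,
#'   `"endometrioid"`, `"mucinous"`, `"other"`); ignored for breast.
#' @param survival_lt12m Logical; death within 12 months of diagnosis.
#' @param prior_breast Logical; prior breast cancer diagnosis (ovarian model).
#' @param p An `hboc_params` object or prepared parameters.
#' @return Referral probabilities in (0, 1).
#' @export
referral_probability <- function(organ, age, high_grade, subtype = NA,
                                 histology = NA, survival_lt12m = FALSE,
                                 prior_breast = FALSE,
                                 p = default_parameters()) {
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  k <- max(length(organ), length(age))
  organ <- rep_len(organ, k); age <- rep_len(age, k)
  high_grade <- rep_len(high_grade, k); subtype <- rep_len(subtype, k)
  histology <- rep_len(histology, k)
  survival_lt12m <- rep_len(survival_lt12m, k)
  prior_breast <- rep_len(prior_breast, k)
  if (!all(organ %in% c("breast", "ovary"))) abort("unknown cancer type")
  odds <- numeric(k)
  b <- organ == "breast"
  if (any(b)) {
    if (any(!subtype[b] %in% c("TN", "HER2", "HRplus"))) {
      abort("unknown breast subtype category")
    }
    rb <- pp$ref_breast
    o <- rep(rb[["constant"]], sum(b))
    ab <- age[b]
    o <- o * ifelse(ab >= 70, rb[["age_70p"]],
                    ifelse(ab >= 50, rb[["age_50_69"]],
                           ifelse(ab >= 40, rb[["age_40_49"]], 1)))
    o <- o * ifelse(survival_lt12m[b], rb[["survival_lt12m"]], 1)
    o <- o * ifelse(high_grade[b], rb[["high_grade"]], 1)
    o <- o * ifelse(subtype[b] == "TN", 1, rb[["non_tn"]])
    o <- o * ifelse(subtype[b] == "HER2", rb[["her2"]], 1)
    odds[b] <- o
  }
  if (any(!b)) {
    v <- !b
    if (any(!histology[v] %in% c("serous", "clear_cell", "endometrioid",
                                 "mucinous", "other"))) {
      abort("unknown ovarian histology category")
    }
    ro <- pp$ref_ovary
    o <- rep(ro[["constant"]], sum(v))
    av <- age[v]
    o <- o * ifelse(av >= 75, ro[["age_75p"]],
                    ifelse(av >= 60, ro[["age_60_74"]], 1))
    o <- o * ifelse(survival_lt12m[v], ro[["survival_lt12m"]], 1)
    o <- o * ifelse(high_grade[v], ro[["high_grade"]], 1)
    o <- o * ifelse(prior_breast[v], ro[["prior_breast"]], 1)
    o <- o * ifelse(histology[v] == "mucinous", ro[["mucinous"]],
                    ifelse(histology[v] == "other", ro[["other_hist"]], 1))
    odds[v] <- o
  }
  odds / (1 + odds)
}

#' Publicly funded testing eligibility (10% carrier-probability threshold)
#'
#' The threshold is assumed met for: (1) triple-negative breast cancer at 50
#' or younger, or triple-negative at any age with at least one breast/ovarian
#' cancer-affected family member; (2) at least three affected first- or
#' second-degree relatives; (3) bilateral breast cancer; (4) grade 2-3
#' serous ovarian cancer at any age; (5) non-mucinous grade 2-3 ovarian
#' cancer under 70.
#'
#' @param organ `"breast"` or `"ovary"` (vectorised).
#' @param age Age at diagnosis.
#' @param subtype Breast subtype; NA for ovarian.
#' @param grade Tumour grade (1-3).
#' @param histology Ovarian histology; NA for breast.
#' @param bilateral Logical; two breast primaries (including history).
#' @param n_affected Number of breast/ovarian cancer-affected first- or
#'   second-degree relatives (alive or deceased) at referral.
#' @return Logical eligibility.
#' @export
is_test_eligible <- function(organ, age, subtype = NA, grade = NA,
                             histology = NA, bilateral = FALSE,
                             n_affected = 0) {
  k <- max(length(organ), length(age))
  organ <- rep_len(organ, k); age <- rep_len(age, k)
  subtype <- rep_len(subtype, k); grade <- rep_len(grade, k)
  histology <- rep_len(histology, k); bilateral <- rep_len(bilateral, k)
  n_affected <- rep_len(n_affected, k)
  b <- organ == "breast"
  crit1 <- b & !is.na(subtype) & subtype == "TN" & (age <= 50 | n_affected >= 1)
  crit2 <- n_affected >= 3
  crit3 <- b & bilateral
  crit4 <- !b & !is.na(histology) & histology == "serous" & grade >= 2
  crit5 <- !b & !is.na(histology) & histology != "mucinous" & grade >= 2 & age < 70
  crit1 | crit2 | crit3 | crit4 | crit5
}

#' Annual predictive-testing uptake probability
#'
#' Table lookup by degree of relation (1st/2nd), current age band and time
#' since the family variant was identified, with the male rate ratio applied
#' and zero uptake under 18.
#'
#' @param degree 1 or 2 (relatives beyond second degree use the 2nd-degree
#'   rates).
#' @param age Current age in years.
#' @param female Logical.
#' @param years_since Completed years since the family variant was first
#'   identified (0 in the identification year).
#' @param p An `hboc_params` object or prepared parameters.
#' @return Annual probabilities.
#' @export
predictive_uptake_probability <- function(degree, age, female, years_since,
                                          p = default_parameters()) {
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  k <- max(length(degree), length(age), length(female), length(years_since))
  degree <- pmin(2L, rep_len(as.integer(degree), k))
  age <- rep_len(age, k); female <- rep_len(female, k)
  years_since <- rep_len(years_since, k)
  ab <- pred_age_band(age)
  tb <- pred_time_band(years_since)
  pr <- pp$pred_uptake[cbind(degree, ab, tb)]
  pr * ifelse(female, 1, pp$male_rr)
}

#' Result of a genetic test
#'
#' The assay is error-free. A diagnostic (full-panel) test detects the
#' person's variant iff the gene is on the chosen panel; a predictive test
#' detects carrier status for the known family gene exactly.
#'
#' @param gene Person's true variant: 0 (none) or index into [hboc_genes()].
#' @param kind `"diagnostic"` or `"predictive"`.
#' @param panel `"high_risk"` (BRCA1/2, PALB2) or `"extended"` (all eight);
#'   diagnostic only.
#' @param family_gene Known family variant gene index (predictive only).
#' @return `"positive"` or `"negative"` per person.
#' @export
test_result <- function(gene, kind, panel = "high_risk", family_gene = NA) {
  k <- length(gene)
  kind <- rep_len(kind, k); panel <- rep_len(panel, k)
  family_gene <- rep_len(family_gene, k)
  on_panel <- ifelse(panel == "extended", gene > 0L,
                     gene > 0L & GENES[pmax(gene, 1L)] %in% HIGH_RISK_GENES)
  pos <- ifelse(kind == "diagnostic", on_panel,
                !is.na(family_gene) & gene == family_gene)
  ifelse(pos, "positive", "negative")
}

# ---- lineage localisation / obligate non-carrier logic ---------------------

#' Which family members could still carry the family variant
#'
#' Exact single-origin Mendelian constraint propagation on an acyclic
#' pedigree: a person can carry the variant iff there exists a founder from
#' whom both the person and every observed carrier descend through links
#' that are untested or tested positive. A person is an obligate non-carrier
#' (and ineligible for predictive testing) iff no such founder exists -
#' this reproduces both the two-negative-parents rule and lineage-side
#' exclusion (a positive maternal grandfather makes the paternal side
#' ineligible).
#'
#' @param fam_tbl Tibble with columns `id`, `mother`, `father` (NA for
#'   founders) for one family, married-in co-parents included.
#' @param positive_ids Ids with an observed positive result for the family
#'   variant.
#' @param negative_ids Ids observed negative for the family variant
#'   (predictive negatives, or panel-tested negative on a panel covering the
#'   gene).
#' @return Logical vector along `fam_tbl` rows: could the person carry the
#'   family variant consistently with the observations.
#' @export
carrier_possible <- function(fam_tbl, positive_ids, negative_ids = integer()) {
  n <- nrow(fam_tbl)
  loc <- function(ids) match(ids, fam_tbl$id)
  m <- loc(fam_tbl$mother); f <- loc(fam_tbl$father)
  # a parent recorded but absent from the table acts as an untested founder
  virt_m <- !is.na(fam_tbl$mother) & is.na(m)
  virt_f <- !is.na(fam_tbl$father) & is.na(f)
  founder <- is.na(fam_tbl$mother) & is.na(fam_tbl$father)
  nf <- sum(founder) + sum(virt_m) + sum(virt_f)
  fcol <- integer(n); fcol[founder] <- seq_len(sum(founder))
  vm_col <- integer(n); vm_col[virt_m] <- sum(founder) + seq_len(sum(virt_m))
  vf_col <- integer(n)
  vf_col[virt_f] <- sum(founder) + sum(virt_m) + seq_len(sum(virt_f))

  blocked <- fam_tbl$id %in% negative_ids
  reach <- matrix(FALSE, n, max(nf, 1L))
  # topological order
  ord <- order(depth_of(fam_tbl, m, f))
  for (r in ord) {
    if (blocked[r]) next
    if (founder[r]) {
      reach[r, fcol[r]] <- TRUE
      next
    }
    if (!is.na(m[r])) reach[r, ] <- reach[r, ] | reach[m[r], ]
    if (vm_col[r] > 0) reach[r, vm_col[r]] <- TRUE
    if (!is.na(f[r])) reach[r, ] <- reach[r, ] | reach[f[r], ]
    if (vf_col[r] > 0) reach[r, vf_col[r]] <- TRUE
  }
  pos <- loc(positive_ids)
  pos <- pos[!is.na(pos)]
  if (!length(pos)) return(!blocked)
  common <- rep(TRUE, ncol(reach))
  for (q in pos) common <- common & reach[q, ]
  if (!any(common)) return(rep(FALSE, n))  # inconsistent observations
  !blocked & (reach %*% common > 0)[, 1]
}

depth_of <- function(fam_tbl, m, f) {
  n <- nrow(fam_tbl)
  depth <- rep(NA_integer_, n)
  depth[is.na(m) & is.na(f)] <- 0L
  guard <- 0L
  while (anyNA(depth)) {
    guard <- guard + 1L
    if (guard > n + 1L) abort("pedigree contains a cycle")
    todo <- which(is.na(depth))
    dm <- ifelse(is.na(m[todo]), 0L, depth[m[todo]])
    df <- ifelse(is.na(f[todo]), 0L, depth[f[todo]])
    ready <- !is.na(dm) & !is.na(df)
    depth[todo[ready]] <- pmax(dm[ready], df[ready]) + 1L
  }
  depth
}

#' Predictive-testing eligibility within a family
#'
#' A relative is eligible iff the family variant is known, the person is
#' alive, has not had full-panel testing nor a previous predictive test, and
#' is not an obligate non-carrier given the observed results (see
#' [carrier_possible()]).
#'
#' @param fam_tbl One family's rows: `id`, `mother`, `father`, plus logical
#'   columns `alive`, `panel_tested`, `pred_tested` (absent columns default
#'   to alive/untested).
#' @param positive_ids,negative_ids Observed results for the family variant.
#' @return Logical eligibility per row.
#' @export
predictive_eligible <- function(fam_tbl, positive_ids,
                                negative_ids = integer()) {
  alive <- col_or(fam_tbl, "alive", rep(TRUE, nrow(fam_tbl)))
  panel <- col_or(fam_tbl, "panel_tested", rep(FALSE, nrow(fam_tbl)))
  prior <- col_or(fam_tbl, "pred_tested", rep(FALSE, nrow(fam_tbl)))
  poss <- carrier_possible(fam_tbl, positive_ids, negative_ids)
  alive & !panel & !prior & poss & !(fam_tbl$id %in% positive_ids)
}

# ---- first/second-degree relative pairs ------------------------------------

# Builds the member-to-member relative pair structure used for (a) counting
# affected relatives at referral, (b) degree of relation to the nearest
# known carrier for cascade uptake, and (c) relatives-per-proband outcomes.
# Returns CSR-style vectors: for person row i, pairs ptr[i]..ptr[i+1]-1 of
# (jj = relative row, dd = degree 1 or 2).
build_relative_pairs <- function(pop) {
  n <- nrow(pop)
  member <- pop$member
  rowid <- seq_len(n)

  pc_i <- integer(0); pc_j <- integer(0)  # child, parent (members both)
  for (col in c("mother", "father")) {
    par <- pop[[col]]
    ok <- !is.na(par) & member & member[ifelse(is.na(par), 1L, par)]
    pc_i <- c(pc_i, rowid[ok]); pc_j <- c(pc_j, par[ok])
  }

  # siblings: children of the same mother (couples share all children)
  mo <- pop$mother
  has_mo <- !is.na(mo) & member
  sib_i <- integer(0); sib_j <- integer(0)
  if (any(has_mo)) {
    kids <- rowid[has_mo]
    moms <- mo[has_mo]
    o <- order(moms)
    kids <- kids[o]; moms <- moms[o]
    runs <- rle(moms)$lengths
    ends <- cumsum(runs); starts <- ends - runs + 1L
    big <- which(runs > 1L)
    if (length(big)) {
      kk <- runs[big]
      tot <- kk^2L
      pos <- sequence(tot) - 1L
      kvec <- rep(kk, tot)
      s0 <- rep(starts[big], tot)
      left <- kids[s0 + pos %/% kvec]
      right <- kids[s0 + pos %% kvec]
      keep <- left != right
      sib_i <- left[keep]; sib_j <- right[keep]
    }
  }

  d1_i <- c(pc_i, pc_j, sib_i)
  d1_j <- c(pc_j, pc_i, sib_j)

  # grandparents via parent-of-parent composition
  gp_i <- integer(0); gp_j <- integer(0)
  for (c1 in c("mother", "father")) for (c2 in c("mother", "father")) {
    par <- pop[[c1]]
    gp <- ifelse(is.na(par), NA_integer_, pop[[c2]][ifelse(is.na(par), 1L, par)])
    ok <- !is.na(gp) & member & member[ifelse(is.na(gp), 1L, gp)]
    gp_i <- c(gp_i, rowid[ok]); gp_j <- c(gp_j, gp[ok])
  }

  # piblings/niblings: sibling pairs composed with children; children of
  # sib_j are niblings of sib_i (CSR over the child-parent edges)
  nib_i <- integer(0); nib_j <- integer(0)
  if (length(sib_i) && length(pc_i)) {
    o <- order(pc_j)
    ch_sorted <- pc_i[o]
    cnt <- tabulate(pc_j, nbins = n)
    cptr <- c(0L, cumsum(cnt))
    lens <- cnt[sib_j]
    if (sum(lens)) {
      nib_j <- rep(sib_i, lens)
      nib_i <- ch_sorted[rep(cptr[sib_j], lens) + sequence(lens)]
    }
  }

  d2_i <- c(gp_i, gp_j, nib_i, nib_j)
  d2_j <- c(gp_j, gp_i, nib_j, nib_i)

  # dedupe (a pair can only arise once per mechanism, but be safe) and drop
  # any degree-2 pair already present as degree-1
  key1 <- d1_i * (n + 1) + d1_j
  k1 <- !duplicated(key1)
  d1_i <- d1_i[k1]; d1_j <- d1_j[k1]; key1 <- key1[k1]
  key2 <- d2_i * (n + 1) + d2_j
  k2 <- !duplicated(key2) & !(key2 %in% key1)
  d2_i <- d2_i[k2]; d2_j <- d2_j[k2]

  ii <- c(d1_i, d2_i); jj <- c(d1_j, d2_j)
  dd <- c(rep(1L, length(d1_i)), rep(2L, length(d2_i)))
  o <- order(ii, dd)
  ii <- ii[o]; jj <- jj[o]; dd <- dd[o]
  ptr <- c(0L, cumsum(tabulate(ii, nbins = n)))
  list(ptr = ptr, jj = jj, dd = dd)
}

# count, for each person in `who`, relatives with flag TRUE
count_flagged_relatives <- function(pairs, who, flag, degree_max = 2L) {
  vapply(who, function(i) {
    a <- pairs$ptr[i] + 1L; b <- pairs$ptr[i + 1L]
    if (b < a) return(0L)
    j <- pairs$jj[a:b]
    d <- pairs$dd[a:b]
    sum(flag[j[d <= degree_max]])
  }, integer(1))
}
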