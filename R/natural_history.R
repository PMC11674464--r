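# Cancer natural history: genotype- and polygenic-adjusted annual hazards,
# breast preclinical onset/sojourn, ovarian onset (no preclinical phase),
# tumour characteristics, and mortality.
#
# Hazard model: h(gene, organ, age) * HR_sd^z / E[HR_sd^z], so the
# population-average polygenic multiplier is 1 and simulated non-carrier
# incidence recovers the input incidence tables. Returned per-year
# probabilities are 1 - exp(-h).

#' Annual cancer-onset probability for a person
#'
#' Combines the genotype-specific hazard table, the polygenic multiplier
#' (normalised to population mean 1), and any risk-reducing-surgery
#' multiplier in force, returning the per-year probability `1 - exp(-h)`.
#'
#' @param person One or more rows of an `hboc_population` (columns `gene`,
#'   `zb`, `zo`, `female`; optional `brrm_age`, `rrso_age` surgery columns).
#' @param organ `"breast"` or `"ovary"`.
#' @param age Attained age (vectorised, recycled against rows of `person`).
#' @param p An `hboc_params` object.
#' @return Numeric vector of per-year probabilities.
#' @export
annual_hazard <- function(person, organ, age, p = default_parameters()) {
  stopifnot(organ %in% c("breast", "ovary"))
  if (any(age < 0 | age > 100)) abort("age outside the 0-100 hazard tables")
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  k <- max(nrow(person), length(age))
  age <- rep_len(age, k)
  gene <- rep_len(person$gene, k)
  brrm <- col_or(person, "brrm_age")
  rrso <- col_or(person, "rrso_age")
  if (organ == "breast") {
    z <- rep_len(person$zb, k)
    h <- pp$haz_breast[cbind(gene + 1L, floor(age) + 1L)] *
      exp(pp$ln_b * z) / pp$norm_b
    if (!is.null(brrm)) {
      post <- !is.na(rep_len(brrm, k)) & rep_len(brrm, k) <= age
      h[post] <- h[post] * pp$const$brrm_multiplier
    }
    if (!is.null(rrso)) {
      post <- !is.na(rep_len(rrso, k)) & rep_len(rrso, k) <= age
      h[post] <- h[post] * pp$const$rrso_breast_multiplier
    }
  } else {
    z <- rep_len(person$zo, k)
    h <- pp$haz_ovary[cbind(gene + 1L, floor(age) + 1L)] *
      exp(pp$ln_o * z) / pp$norm_o
    if (!is.null(rrso)) {
      post <- !is.na(rep_len(rrso, k)) & rep_len(rrso, k) <= age
      h[post] <- h[post] * pp$const$rrso_ovary_multiplier
    }
  }
  h[!rep_len(person$female, k)] <- 0
  1 - exp(-h)
}

# ---- vectorised attribute samplers (shared by baseline replay and engine) --

sample_breast_attributes <- function(ids, gene, mode, yr, seed, pp) {
  k <- length(ids)
  gname <- c("none", GENES)[gene + 1L]
  subtype <- character(k)
  u <- cr_unif(seed, ids, PROC$subtype, yr)
  for (g in unique(gname)) {
    i <- gname == g
    cb <- pp$cum_subtype[[g]]
    subtype[i] <- draw_cat(u[i], cb$cdf, cb$levels)
  }
  grade <- integer(k)
  u <- cr_unif(seed, ids, PROC$grade, yr)
  for (s in unique(subtype)) {
    i <- subtype == s
    cb <- pp$cum_bgrade[[s]]
    grade[i] <- draw_cat(u[i], cb$cdf, cb$levels)
  }
  cb <- pp$cum_bsize[[mode]]
  size <- draw_cat(cr_unif(seed, ids, PROC$size, yr), cb$cdf, cb$levels)
  p_n <- pp$nodes_p[size] * if (mode == "screen") pp$nodes_screen_mult else 1
  nodes <- cr_unif(seed, ids, PROC$nodes, yr) < p_n
  p_m <- pp$met_p[ifelse(nodes, "positive", "negative")]
  met <- cr_unif(seed, ids, PROC$met, yr) < p_m
  stage <- ifelse(met, 3L, ifelse(nodes, 2L, 1L))
  list(subtype = subtype, grade = grade, size = size, nodes = nodes,
       met = met, stage = stage)
}

sample_ovarian_attributes <- function(ids, gene, age, yr, seed, pp) {
  k <- length(ids)
  hist <- character(k)
  grade <- integer(k)
  carrier_rule <- gene > 0L & age > 25
  hist[carrier_rule] <- "serous"
  grade[carrier_rule] <- 3L
  rest <- which(!carrier_rule)
  if (length(rest)) {
    band <- ifelse(age[rest] < 50, "<50", ifelse(age[rest] < 70, "50-69", "70+"))
    u <- cr_unif(seed, ids[rest], PROC$histology, yr)
    for (b in unique(band)) {
      i <- band == b
      cb <- pp$cum_ohist[[b]]
      hist[rest[i]] <- draw_cat(u[i], cb$cdf, cb$levels)
    }
    u <- cr_unif(seed, ids[rest], PROC$ograde, yr)
    hr <- hist[rest]
    for (h in unique(hr)) {
      i <- hr == h
      cb <- pp$cum_ograde[[h]]
      grade[rest[i]] <- draw_cat(u[i], cb$cdf, cb$levels)
    }
  }
  stage <- integer(k)
  u <- cr_unif(seed, ids, PROC$ostage, yr)
  key <- paste(hist, grade, sep = "|")
  for (kk in unique(key)) {
    i <- key == kk
    cb <- pp$cum_ostage[[kk]]
    stage[i] <- match(draw_cat(u[i], cb$cdf, cb$levels),
                      c("local", "regional", "distant"))
  }
  list(histology = hist, grade = grade, stage = stage)
}

# annual excess-mortality probability for a prevalent cancer
excess_death_prob <- function(organ_idx, stage, yrs_since, dx_age, hist, pp) {
  band <- ifelse(yrs_since < 5, 1L, ifelse(yrs_since < 10, 2L, 3L))
  rate <- pp$exc[cbind(organ_idx, stage, band)] * pp$age_mult(dx_age)
  if (!is.null(hist)) {
    hm <- rep(1, length(rate))
    ok <- !is.na(hist)
    hm[ok] <- pp$hist_mult[hist[ok]]
    rate <- rate * hm
  }
  1 - exp(-rate)
}

# ---- person-level operations ----------------------------------------------

#' Simulate a breast-cancer course for one woman
#'
#' Runs the preclinical-onset hazards forward from the person's current age
#' (no screening, no interventions): onset from the genotype-adjusted
#' hazards, lognormal preclinical sojourn, symptomatic diagnosis when the
#' sojourn expires, subtype and grade conditional on genotype.
#'
#' @param person One row of an `hboc_population` (needs `id`, `gene`, `zb`,
#'   `female` and a current age column `age` or `age_entry`).
#' @param p An `hboc_params` object.
#' @param seed Integer seed.
#' @return A tibble with zero rows (no tumour before age 100) or one row:
#'   `age_at_onset`, `sojourn_time`, `age_at_diagnosis`, `subtype`, `grade`,
#'   `detection_mode`.
#' @export
sample_breast_course <- function(person, p = default_parameters(), seed = 1L) {
  stopifnot(nrow(person) == 1)
  if (!person$female) abort("breast course requires a female person")
  brrm <- col_or(person, "brrm_age", NA_real_)
  if (!is.na(brrm)) {
    abort("person has undergone bilateral risk-reducing mastectomy")
  }
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  a0 <- floor(col_or(person, "age", col_or(person, "age_entry", 0)))
  for (a in a0:100) {
    pr <- annual_hazard(person, "breast", a, pp)
    u <- cr_unif(seed, person$id, PROC$bc_onset, a + BASE_YEAR_OFFSET)
    if (u < pr) {
      us <- cr_unif(seed, person$id, PROC$sojourn, a + BASE_YEAR_OFFSET)
      soj <- stats::qlnorm(us, pp$soj_meanlog[person$gene + 1L],
                           pp$soj_sdlog[person$gene + 1L])
      onset <- a + u / pr
      att <- sample_breast_attributes(person$id, person$gene, "symptomatic",
                                      a + BASE_YEAR_OFFSET, seed, pp)
      return(tibble(age_at_onset = onset, sojourn_time = soj,
                    age_at_diagnosis = onset + soj,
                    subtype = att$subtype, grade = att$grade,
                    detection_mode = "symptomatic"))
    }
  }
  tibble(age_at_onset = numeric(), sojourn_time = numeric(),
         age_at_diagnosis = numeric(), subtype = character(),
         grade = integer(), detection_mode = character())
}

#' Assign prognostic characteristics at breast-cancer detection
#'
#' Samples tumour size class, nodal status and metastasis conditional on
#' detection mode; these are fixed once assigned (a second call errors).
#'
#' @param tumour One-row tumour tibble (e.g. from [sample_breast_course()]);
#'   must carry a `person_id` column or an `id` attribute identifying the
#'   person for the draw stream.
#' @param detection_mode `"screen"`, `"symptomatic"` or `"baseline"`.
#' @param p An `hboc_params` object.
#' @param seed Integer seed.
#' @return `tumour` with `size_class`, `node_positive`, `metastatic`,
#'   `stage` columns added.
#' @export
assign_breast_prognostics <- function(tumour, detection_mode,
                                      p = default_parameters(), seed = 1L) {
  stopifnot(nrow(tumour) == 1,
            detection_mode %in% c("screen", "symptomatic", "baseline"))
  if (!is.null(col_or(tumour, "size_class")) && !is.na(tumour$size_class)) {
    abort("prognostic characteristics are fixed at detection and cannot be resampled")
  }
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  pid <- col_or(tumour, "person_id", 1L)
  gene <- col_or(tumour, "gene", 0L)
  att <- sample_breast_attributes(pid, gene, detection_mode,
                                  floor(tumour$age_at_diagnosis[1]), seed, pp)
  tumour$size_class <- att$size
  tumour$node_positive <- att$nodes
  tumour$metastatic <- att$met
  tumour$stage <- c("local", "regional", "distant")[att$stage]
  tumour$detection_mode <- detection_mode
  tumour
}

#' Sample an ovarian cancer record
#'
#' Ovarian cancer has no preclinical phase: onset equals diagnosis. Carriers
#' diagnosed after age 25 are high-grade serous; otherwise histology is
#' conditional on age, grade on histology, and stage on histology and grade
#' (advanced stage more likely for high grade and serous histology).
#'
#' @param person One row of an `hboc_population`.
#' @param age Age at the event.
#' @param p An `hboc_params` object.
#' @param seed Integer seed.
#' @return Zero-row tibble if the person has had risk-reducing
#'   salpingo-oophorectomy before `age`, else one row with `age_at_diagnosis`,
#'   `histology`, `grade`, `stage`.
#' @export
sample_ovarian_cancer <- function(person, age, p = default_parameters(),
                                  seed = 1L) {
  stopifnot(nrow(person) == 1)
  if (!person$female) abort("ovarian cancer requires a female person")
  rrso <- col_or(person, "rrso_age", NA_real_)
  if (!is.na(rrso) && rrso <= age) {
    return(tibble(age_at_diagnosis = numeric(), histology = character(),
                  grade = integer(), stage = character()))
  }
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  att <- sample_ovarian_attributes(person$id, person$gene, age, floor(age),
                                   seed, pp)
  tibble(age_at_diagnosis = age, histology = att$histology, grade = att$grade,
         stage = c("local", "regional", "distant")[att$stage])
}

#' Sample age and cause of death
#'
#' Other-cause mortality from the sex-specific lifetable runs at all ages;
#' cancer-specific excess mortality applies only after a diagnosis,
#' conditional on organ, stage and age band. The first event wins; everyone
#' exits at 100.
#'
#' @param person One row of an `hboc_population`; diagnosis columns
#'   (`bc1_age0`, `bc1_stage0`, `oc_age0`, `oc_stage0`, `oc_hist0`) are used
#'   when present.
#' @param p An `hboc_params` object.
#' @param seed Integer seed.
#' @return One-row tibble: `age_at_death`, `cause` (`"other"`, `"cancer"` or
#'   `"exit"` at the age-100 cap).
#' @export
sample_death <- function(person, p = default_parameters(), seed = 1L) {
  stopifnot(nrow(person) == 1)
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  a0 <- floor(col_or(person, "age", max(0, col_or(person, "age_entry", 0))))
  sexrow <- if (person$female) 1L else 2L
  bc_age <- col_or(person, "bc1_age0", NA_real_)
  bc_stage <- col_or(person, "bc1_stage0", NA_integer_)
  oc_age <- col_or(person, "oc_age0", NA_real_)
  oc_stage <- col_or(person, "oc_stage0", NA_integer_)
  oc_hist <- col_or(person, "oc_hist0", NA_character_)
  for (a in a0:100) {
    yr <- a + BASE_YEAR_OFFSET
    q <- pp$qx[sexrow, a + 1L]
    if (cr_unif(seed, person$id, PROC$ocd, yr) < q) {
      return(tibble(age_at_death = as.numeric(a), cause = "other"))
    }
    if (!is.na(bc_age) && a >= bc_age) {
      pk <- excess_death_prob(1L, bc_stage, a - bc_age, bc_age, NULL, pp)
      if (cr_unif(seed, person$id, PROC$cdeath_bc, yr) < pk) {
        return(tibble(age_at_death = as.numeric(a), cause = "cancer"))
      }
    }
    if (!is.na(oc_age) && a >= oc_age) {
      pk <- excess_death_prob(2L, oc_stage, a - oc_age, oc_age, oc_hist, pp)
      if (cr_unif(seed, person$id, PROC$cdeath_oc, yr) < pk) {
        return(tibble(age_at_death = as.numeric(a), cause = "cancer"))
      }
    }
  }
  tibble(age_at_death = 100, cause = "exit")
}
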