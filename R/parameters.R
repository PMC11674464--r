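# Parameter bundle: loading, validation, writing.
#
# A parameter set is a named list of tibbles plus a `constants` list, with
# class "hboc_params". The bundled defaults live under
# inst/extdata/hboc_defaults as one YAML config referencing plain CSV tables
# (diff-able and editable); `default_parameters()` loads them. Every
# age-indexed hazard table is dense on integer ages 0-100.

PARAM_TABLES <- c(
  "genes", "baseline_incidence", "penetrance", "polygenic", "referral",
  "testing_uptake", "predictive_uptake", "parity_completed", "parity_age",
  "maternal_age", "lifetable", "screening_performance", "screening_start",
  "screening_delay", "surgery_uptake", "survival_excess",
  "survival_modifiers", "breast_subtype", "breast_grade", "breast_size",
  "breast_nodes", "breast_met", "ovarian_histology", "ovarian_grade",
  "ovarian_stage", "sojourn"
)

the <- new.env(parent = emptyenv())

bundle_dir <- function() {
  system.file("extdata", "hboc_defaults", package = "hbocsim", mustWork = TRUE)
}

#' Default model parameterisation
#'
#' Loads the parameter bundle shipped with the package. Referral and testing
#' uptake odds/probabilities and the predictive-testing uptake grid are
#' encoded verbatim; penetrance curves, parity distributions, screening
#' performance and the tumour/survival models are literature-anchored
#' defaults documented in the bundle's `provenance.md`, calibrated so that
#' the generated population reproduces published family-structure and
#' incidence summaries.
#'
#' @return A validated `hboc_params` object.
#' @export
default_parameters <- function() {
  if (is.null(the$default_params)) {
    the$default_params <- load_parameters(file.path(bundle_dir(), "config.yaml"))
  }
  the$default_params
}

#' Load a parameter configuration
#'
#' Reads a YAML config whose `tables:` section maps parameter fields to CSV
#' files (paths relative to the config file) and whose `constants:` section
#' holds scalar settings. Any field absent from the config falls back to the
#' bundled default. The merged set is validated before being returned.
#'
#' @param config_path Path to a YAML configuration file.
#' @return A validated `hboc_params` object.
#' @export
load_parameters <- function(config_path) {
  if (!file.exists(config_path)) {
    abort(paste0("config file does not exist: ", config_path))
  }
  cfg <- yaml::read_yaml(config_path)
  dir <- dirname(config_path)
  is_bundle <- normalizePath(dir) == normalizePath(bundle_dir())

  base <- if (is_bundle) NULL else default_parameters()

  tables <- list()
  for (tb in PARAM_TABLES) {
    rel <- cfg$tables[[tb]]
    if (is.null(rel)) {
      if (is.null(base)) {
        abort(paste0("missing parameter: table '", tb, "' absent from bundle config"))
      }
      tables[[tb]] <- base[[tb]]
    } else {
      path <- file.path(dir, rel)
      if (!file.exists(path)) {
        abort(paste0("missing parameter: table '", tb, "' file not found: ", path))
      }
      tables[[tb]] <- readr::read_csv(path, show_col_types = FALSE,
                                      progress = FALSE)
    }
  }

  constants <- if (is.null(base)) list() else base$constants
  for (nm in names(cfg$constants)) constants[[nm]] <- cfg$constants[[nm]]

  # a user config that overrides completed parity without supplying the
  # age-specific table gets a consistent derived table
  if (!is.null(cfg$tables$parity_completed) && is.null(cfg$tables$parity_age) &&
      !is_bundle) {
    tables$parity_age <- derive_parity_age(tables$parity_completed,
                                           tables$maternal_age)
  }

  p <- structure(c(tables, list(constants = constants)), class = "hboc_params")
  rep_ <- validate_parameters(p)
  if (nrow(rep_) > 0) {
    abort(paste0("invalid parameter set:\n",
                 paste0("  - ", rep_$field, ": ", rep_$issue, collapse = "\n")))
  }
  p
}

#' Derive age-specific parity CDFs
#'
#' Computes the distribution of number of children born by a given age,
#' implied by the completed-parity distribution and the maternal-age-at-birth
#' distribution (births treated as independent draws from the maternal-age
#' distribution).
#'
#' @param parity_completed Tibble with columns `children`, `cdf`.
#' @param maternal_age Tibble with columns `age`, `prob`.
#' @return Tibble with columns `age_group`, `children`, `cdf`.
#' @export
derive_parity_age <- function(parity_completed, maternal_age) {
  groups <- tibble(
    age_group = c("0-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45+"),
    mid = c(18, 22, 27, 32, 37, 42, 47)
  )
  pk <- diff(c(0, parity_completed$cdf))
  kmax <- max(parity_completed$children)
  out <- purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    fa <- sum(maternal_age$prob[maternal_age$age <= groups$mid[g]])
    fa <- min(1, fa)
    pn <- vapply(0:kmax, function(nb) {
      sum(vapply(nb:kmax, function(k) {
        pk[k + 1] * stats::dbinom(nb, k, fa)
      }, numeric(1)))
    }, numeric(1))
    tibble(age_group = groups$age_group[g], children = 0:kmax,
           cdf = pmin(1, cumsum(pn) / sum(pn)))
  })
  out$cdf[out$children == kmax] <- 1
  out
}

#' Validate a parameter set
#'
#' Report-only structural and range checks: probabilities in \[0, 1\], hazards
#' non-negative, CDFs non-decreasing and ending at 1, age-indexed curves
#' dense on 0-100, and the under-18 predictive-uptake cells equal to zero.
#'
#' @param p An `hboc_params` object.
#' @return A tibble with columns `field` and `issue`; zero rows when valid.
#' @export
validate_parameters <- function(p) {
  bad <- list()
  note <- function(field, issue) bad[[length(bad) + 1]] <<- tibble(field = field, issue = issue)

  chk_prob <- function(x, field, what = "probability") {
    i <- which(!is.finite(x) | x < 0 | x > 1)
    if (length(i)) note(field, paste0(what, " out of [0,1] at row ", i[1]))
  }
  chk_haz <- function(x, field) {
    i <- which(!is.finite(x) | x < 0)
    if (length(i)) note(field, paste0("negative or non-finite hazard at row ", i[1]))
  }
  chk_cdf <- function(x, field) {
    if (any(!is.finite(x)) || any(diff(x) < -1e-12) || x[length(x)] > 1 + 1e-9 ||
        abs(x[length(x)] - 1) > 1e-6) {
      note(field, "CDF not non-decreasing or does not end at 1")
    }
  }
  chk_ages <- function(tab, field, by = NULL) {
    split_cols <- if (is.null(by)) list(rep(1, nrow(tab))) else tab[by]
    for (grp in split(seq_len(nrow(tab)), split_cols, drop = TRUE)) {
      ages <- sort(tab$age[grp])
      if (!identical(as.integer(ages), 0:100)) {
        note(field, "age grid is not the dense integer range 0-100")
        return(invisible())
      }
    }
  }

  chk_prob(p$genes$prevalence, "genes")
  chk_haz(p$baseline_incidence$hazard, "baseline_incidence")
  chk_ages(p$baseline_incidence, "baseline_incidence", by = "organ")
  chk_haz(p$penetrance$hazard, "penetrance")
  chk_ages(p$penetrance, "penetrance", by = c("gene", "organ"))
  if (any(p$polygenic$hr_per_sd <= 0)) note("polygenic", "hazard ratio must be > 0")
  if (any(p$referral$or <= 0)) note("referral", "odds ratios must be > 0")
  chk_prob(p$testing_uptake$uptake, "testing_uptake", "uptake")
  chk_prob(p$predictive_uptake$prob, "predictive_uptake", "uptake")
  u18 <- p$predictive_uptake[p$predictive_uptake$age_band == "<18", ]
  if (any(u18$prob != 0)) note("predictive_uptake", "age band <18 must be zero")
  for (ag in unique(p$parity_age$age_group)) {
    chk_cdf(p$parity_age$cdf[p$parity_age$age_group == ag],
            paste0("parity_age[", ag, "]"))
  }
  chk_cdf(p$parity_completed$cdf, "parity_completed")
  if (abs(sum(p$maternal_age$prob) - 1) > 1e-6) note("maternal_age", "probabilities must sum to 1")
  chk_prob(p$lifetable$qx, "lifetable", "death probability")
  chk_ages(p$lifetable, "lifetable", by = "sex")
  chk_prob(p$screening_performance$sens, "screening_performance", "sensitivity")
  chk_prob(p$screening_performance$spec, "screening_performance", "specificity")
  if (abs(sum(p$screening_start$prob) - 1) > 1e-6) note("screening_start", "start-age probabilities must sum to 1")
  for (cx in unique(p$screening_delay$context)) {
    s <- sum(p$screening_delay$prob[p$screening_delay$context == cx])
    if (abs(s - 1) > 1e-6) note(paste0("screening_delay[", cx, "]"), "probabilities must sum to 1")
  }
  chk_prob(p$surgery_uptake$annual_prob, "surgery_uptake", "uptake")
  chk_haz(p$survival_excess$rate, "survival_excess")
  if (any(p$survival_modifiers$multiplier < 0)) note("survival_modifiers", "multipliers must be >= 0")
  for (tb in c("breast_subtype", "breast_grade", "breast_size",
               "ovarian_histology", "ovarian_grade", "ovarian_stage")) {
    tab <- p[[tb]]
    keys <- setdiff(names(tab), c("prob", tail(names(tab), 2)))
    keycols <- switch(tb,
      breast_subtype = "gene", breast_grade = "subtype", breast_size = "mode",
      ovarian_histology = "age_band", ovarian_grade = "histology",
      ovarian_stage = c("histology", "grade"))
    chk_prob(tab$prob, tb)
    sums <- aggregate(tab$prob, by = tab[keycols], FUN = sum)
    if (any(abs(sums$x - 1) > 1e-6)) note(tb, "conditional probabilities must sum to 1")
  }
  chk_prob(p$breast_nodes$p_pos, "breast_nodes")
  chk_prob(p$breast_met$p_met, "breast_met")
  if (any(p$sojourn$sdlog < 0)) note("sojourn", "sdlog must be >= 0")
  co <- p$constants
  for (nm in c("male_rate_ratio", "never_screen", "brrm_multiplier",
               "rrso_ovary_multiplier", "crrm_uptake_carrier",
               "crrm_uptake_noncarrier")) {
    v <- co[[nm]]
    if (is.null(v) || !is.finite(v) || v < 0 || v > 1) {
      note(paste0("constants$", nm), "must be a probability in [0,1]")
    }
  }
  if (length(bad) == 0) {
    tibble(field = character(), issue = character())
  } else {
    bind_rows(bad)
  }
}

#' Write a parameter set to a bundle directory
#'
#' Writes `config.yaml` plus one CSV per parameter table; re-loading the
#' written bundle with [load_parameters()] reproduces the input values
#' exactly.
#'
#' @param p An `hboc_params` object.
#' @param dir Directory to write into (created if needed).
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(p, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- setNames(paste0(PARAM_TABLES, ".csv"), PARAM_TABLES)
  for (tb in PARAM_TABLES) {
    readr::write_csv(p[[tb]], file.path(dir, tables[[tb]]), progress = FALSE)
  }
  cfg <- list(tables = as.list(tables), constants = p$constants)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.hboc_params <- function(x, ...) {
  cat("<hboc_params>\n")
  cat("  genes:", paste(x$genes$gene, collapse = ", "), "\n")
  cat("  tables:", length(PARAM_TABLES), "| constants:",
      length(x$constants), "\n")
  invisible(x)
}

# ---- compiled lookups ------------------------------------------------------
# prepare_params() flattens the tibbles into matrices/vectors for O(1)
# age-indexed lookups inside the yearly cycle. Internal.

prepare_params <- function(p) {
  pp <- new.env(parent = emptyenv())
  pp$params <- p
  co <- p$constants
  pp$const <- co

  pp$prev <- setNames(p$genes$prevalence[match(GENES, p$genes$gene)], GENES)

  haz_mat <- function(organ) {
    m <- matrix(0, nrow = 9, ncol = 101)
    b <- p$baseline_incidence[p$baseline_incidence$organ == organ, ]
    m[1, b$age + 1] <- b$hazard
    for (g in seq_along(GENES)) {
      pe <- p$penetrance[p$penetrance$gene == GENES[g] &
                           p$penetrance$organ == organ, ]
      m[g + 1, pe$age + 1] <- pe$hazard
    }
    m
  }
  pp$haz_breast <- haz_mat("breast")
  pp$haz_ovary <- haz_mat("ovary")

  pp$hr_b <- p$polygenic$hr_per_sd[p$polygenic$organ == "breast"]
  pp$hr_o <- p$polygenic$hr_per_sd[p$polygenic$organ == "ovary"]
  pp$ln_b <- log(pp$hr_b); pp$ln_o <- log(pp$hr_o)
  pp$norm_b <- exp(pp$ln_b^2 / 2); pp$norm_o <- exp(pp$ln_o^2 / 2)

  pp$qx <- rbind(
    F = p$lifetable$qx[p$lifetable$sex == "F"][order(p$lifetable$age[p$lifetable$sex == "F"])],
    M = p$lifetable$qx[p$lifetable$sex == "M"][order(p$lifetable$age[p$lifetable$sex == "M"])]
  )

  rf <- p$referral
  pp$ref_breast <- setNames(rf$or[rf$cancer == "breast"], rf$term[rf$cancer == "breast"])
  pp$ref_ovary <- setNames(rf$or[rf$cancer == "ovary"], rf$term[rf$cancer == "ovary"])
  pp$uptake_breast <- p$testing_uptake$uptake[p$testing_uptake$cancer == "breast"]
  pp$uptake_ovary <- p$testing_uptake$uptake[p$testing_uptake$cancer == "ovary"]

  pu <- p$predictive_uptake
  arr <- array(0, dim = c(2, 5, 3),
               dimnames = list(c("1", "2"), c("<18", "18-29", "30-49", "50-59", "60+"),
                               c("<1", "1-3", ">3")))
  for (i in seq_len(nrow(pu))) {
    arr[as.character(pu$degree[i]), pu$age_band[i], pu$time_band[i]] <- pu$prob[i]
  }
  pp$pred_uptake <- arr
  pp$male_rr <- co$male_rate_ratio

  pp$parity_cdf <- p$parity_completed$cdf
  pp$parity_k <- p$parity_completed$children
  pp$mat_age <- p$maternal_age$age
  pp$mat_cdf <- cumsum(p$maternal_age$prob)
  pp$mat_F <- function(a) {
    stats::approx(c(-1, pp$mat_age), c(0, pp$mat_cdf), xout = a, method = "constant",
                  rule = 2)$y
  }

  # screening performance as dense-by-age vectors
  dense_perf <- function(modality, col) {
    v <- numeric(101)
    t <- p$screening_performance[p$screening_performance$modality == modality, ]
    for (i in seq_len(nrow(t))) {
      v[(t$age_lo[i]:min(100, t$age_hi[i])) + 1] <- t[[col]][i]
    }
    v
  }
  pp$mam_sens <- dense_perf("mammography", "sens")
  pp$mam_spec <- dense_perf("mammography", "spec")
  pp$mri_sens <- dense_perf("mri", "sens")
  pp$mri_spec <- dense_perf("mri", "spec")

  pp$start_age <- p$screening_start$age
  pp$start_cdf <- cumsum(p$screening_start$prob)
  delay_cdf <- function(cx) {
    t <- p$screening_delay[p$screening_delay$context == cx, ]
    list(years = t$years, cdf = cumsum(t$prob))
  }
  pp$delay_pop <- delay_cdf("population")
  pp$delay_hr_start <- delay_cdf("highrisk_start")
  pp$delay_hr_int <- delay_cdf("highrisk_interval")

  surg_mat <- function(surgery) {
    m <- matrix(0, nrow = 8, ncol = 101, dimnames = list(GENES, NULL))
    t <- p$surgery_uptake[p$surgery_uptake$surgery == surgery, ]
    for (i in seq_len(nrow(t))) {
      m[t$gene[i], (t$age_lo[i]:min(100, t$age_hi[i])) + 1] <- t$annual_prob[i]
    }
    m
  }
  pp$brrm_uptake <- surg_mat("BRRM")
  pp$rrso_uptake <- surg_mat("RRSO")

  se <- p$survival_excess
  exc <- array(0, dim = c(2, 3, 3),
               dimnames = list(c("breast", "ovary"), c("local", "regional", "distant"),
                               c("y0_4", "y5_9", "y10p")))
  band_of <- function(lo) ifelse(lo == 0, 1L, ifelse(lo == 5, 2L, 3L))
  for (i in seq_len(nrow(se))) {
    exc[se$organ[i], se$stage[i], band_of(se$yrs_lo[i])] <- se$rate[i]
  }
  pp$exc <- exc
  sm <- p$survival_modifiers
  pp$hist_mult <- setNames(sm$multiplier[sm$type == "histology"], sm$level[sm$type == "histology"])
  am <- sm[sm$type == "age", ]
  pp$age_mult <- function(age) {
    out <- rep(1, length(age))
    out[age < 50] <- am$multiplier[am$level == "<50"]
    out[age >= 50 & age < 70] <- am$multiplier[am$level == "50-69"]
    out[age >= 70] <- am$multiplier[am$level == "70+"]
    out
  }

  cum_by <- function(tab, keys, levels_col, prob = "prob") {
    # returns list keyed by interaction of keys: list(levels, cdf)
    sp <- split(seq_len(nrow(tab)), tab[keys], drop = TRUE, sep = "|")
    lapply(sp, function(i) list(levels = tab[[levels_col]][i],
                                cdf = cumsum(tab[[prob]][i])))
  }
  pp$cum_subtype <- cum_by(p$breast_subtype, "gene", "subtype")
  pp$cum_bgrade <- cum_by(p$breast_grade, "subtype", "grade")
  pp$cum_bsize <- cum_by(p$breast_size, "mode", "size_class")
  pp$nodes_p <- setNames(p$breast_nodes$p_pos, p$breast_nodes$size_class)
  pp$nodes_screen_mult <- co$nodes_screen_multiplier
  pp$met_p <- setNames(p$breast_met$p_met, p$breast_met$nodes)
  pp$cum_ohist <- cum_by(p$ovarian_histology, "age_band", "histology")
  pp$cum_ograde <- cum_by(p$ovarian_grade, "histology", "grade")
  pp$cum_ostage <- cum_by(p$ovarian_stage, c("histology", "grade"), "stage")

  pp$soj_meanlog <- setNames(c(p$sojourn$meanlog[match(c("none", GENES), p$sojourn$gene)]),
                             c("none", GENES))
  pp$soj_sdlog <- setNames(c(p$sojourn$sdlog[match(c("none", GENES), p$sojourn$gene)]),
                           c("none", GENES))
  pp
}
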