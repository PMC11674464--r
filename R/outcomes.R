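# Outcome computation: analysis cohorts, detection rates, life expectancy
# and anchored life-years, cumulative incidence / surgery-uptake curves, and
# the cross-scenario summary table.

#' Was each person alive at a given simulation year?
#'
#' @param po Final person table of an `hboc_sim`.
#' @param year Simulation year (scalar or per-person vector).
#' @return Logical vector.
#' @export
alive_at_year <- function(po, year) {
  age_at <- po$age_entry + year
  po$born & !po$never_born & age_at >= 0 &
    (is.na(po$death_age) | po$death_age > age_at)
}

#' Select the analysis cohort from a simulation
#'
#' Probands who developed breast cancer during the simulation before
#' `max_dx_age`, excluding probands whose variant was detected prior to
#' their breast-cancer diagnosis; plus all member relatives of the selected
#' probands, flagged for the standard subsets (alive at the proband's
#' diagnosis, female, cancer-unaffected at that time, carrier).
#'
#' @param sim An `hboc_sim`.
#' @param max_dx_age Upper age limit at diagnosis (exclusive), default 80.
#' @return List with tibbles `probands` and `relatives`; relatives carry
#'   `anchor_year` (the proband's diagnosis year), `alive_at_anchor`,
#'   `unaffected_at_anchor`.
#' @export
select_cohort <- function(sim, max_dx_age = 80) {
  po <- sim$population
  pro <- po %>%
    filter(.data$rel == "proband", !is.na(.data$bc1_year),
           .data$bc1_age < max_dx_age,
           is.na(.data$pos_year) | .data$pos_year >= .data$bc1_year)
  anchor <- setNames(pro$bc1_year, pro$fam)
  relatives <- po %>%
    filter(.data$fam %in% pro$fam, .data$member, .data$rel != "proband") %>%
    mutate(anchor_year = unname(anchor[as.character(.data$fam)]))
  relatives$alive_at_anchor <- alive_at_year(relatives, relatives$anchor_year)
  age_at_anchor <- relatives$age_entry + relatives$anchor_year
  relatives$unaffected_at_anchor <-
    (is.na(relatives$bc1_age) | relatives$bc1_age > age_at_anchor) &
    (is.na(relatives$oc_age) | relatives$oc_age > age_at_anchor)
  list(probands = pro, relatives = relatives)
}

#' Carrier detection rate in a cohort
#'
#' Proportion of carriers identified through genetic testing, split by
#' mechanism (diagnostic full-panel sequencing vs predictive testing).
#'
#' @param cohort A person tibble (e.g. `select_cohort(sim)$probands` or a
#'   relative subset).
#' @param gene Optional gene name to restrict carriers to.
#' @return One-row tibble: `n_carriers`, `n_identified`, `rate`,
#'   `n_predictive`, `n_diagnostic`.
#' @export
detection_rate <- function(cohort, gene = NULL) {
  carriers <- cohort %>% filter(.data$gene > 0L)
  if (!is.null(gene)) {
    gi <- match(gene, GENES)
    carriers <- carriers %>% filter(.data$gene == gi)
  }
  idd <- carriers %>% filter(.data$result_pos)
  n_pred <- sum(idd$pred_tested & !is.na(idd$pred_year) &
                  idd$pred_year == idd$pos_year)
  tibble(
    n_carriers = nrow(carriers),
    n_identified = nrow(idd),
    rate = ifelse(nrow(carriers) == 0, NA_real_, nrow(idd) / nrow(carriers)),
    n_predictive = n_pred,
    n_diagnostic = nrow(idd) - n_pred)
}

#' Life expectancy and anchored life-years
#'
#' Life expectancy is the mean age at death (capped at the age-100 exit);
#' anchored life-years are the mean years lived after a per-person anchor
#' year (for cohort analyses, the proband's diagnosis year). Confidence
#' intervals use the person-level normal approximation.
#'
#' @param cohort Person tibble; every member must have a terminal event
#'   (death or exit).
#' @param anchor_year Optional per-person anchor (simulation year); when
#'   absent only life expectancy is reported.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble with estimates and CI bounds.
#' @export
life_metrics <- function(cohort, anchor_year = NULL, level = 0.95) {
  if (any(is.na(cohort$death_age))) {
    abort("life_metrics: cohort contains persons without a terminal event")
  }
  z <- qnorm(1 - (1 - level) / 2)
  ci <- function(x) {
    m <- mean(x); se <- stats::sd(x) / sqrt(length(x))
    c(m, m - z * se, m + z * se)
  }
  le <- ci(cohort$death_age)
  out <- tibble(n = nrow(cohort),
                life_expectancy = le[1], le_lo = le[2], le_hi = le[3])
  if (!is.null(anchor_year)) {
    anchor_age <- cohort$age_entry + anchor_year
    ly <- pmax(0, cohort$death_age - anchor_age)
    ay <- ci(ly)
    out$anchored_life_years <- ay[1]
    out$aly_lo <- ay[2]; out$aly_hi <- ay[3]
  }
  out
}

# discrete-time product-limit curve: yearly risk sets from `from` (usually
# 0) with event and censoring offsets; event NA = never
km_curve <- function(event_t, cens_t, t_max = NULL) {
  event_t <- ifelse(is.na(event_t), Inf, event_t)
  cens_t <- ifelse(is.na(cens_t), Inf, cens_t)
  obs <- pmin(event_t, cens_t)
  is_event <- event_t <= cens_t & is.finite(event_t)
  if (is.null(t_max)) {
    t_max <- max(obs[is.finite(obs)], 0)
  }
  tt <- 0:t_max
  at_risk <- vapply(tt, function(s) sum(obs >= s), numeric(1))
  events <- vapply(tt, function(s) sum(is_event & obs >= s & obs < s + 1),
                   numeric(1))
  haz <- ifelse(at_risk > 0, events / at_risk, 0)
  tibble(time = tt, at_risk = at_risk, events = events,
         cum_inc = 1 - cumprod(1 - haz))
}

#' Cumulative incidence and surgery-uptake curves since an anchor
#'
#' Kaplan-Meier-style cumulative incidence over years since the anchor
#' (e.g. the proband's diagnosis year) for breast cancer, ovarian cancer,
#' and uptake of risk-reducing surgery, censoring at other-cause death, the
#' competing cancer, and model exit.
#'
#' @param cohort Relative tibble from [select_cohort()] (needs
#'   `anchor_year`); typically filtered to the subset of interest.
#' @param t_max Largest time offset (years) to report.
#' @return Tibble of class `hboc_curves`: `outcome`, `time`, `at_risk`,
#'   `events`, `cum_inc`.
#' @export
incidence_and_uptake_curves <- function(cohort, t_max = 40) {
  a <- cohort$anchor_year
  off <- function(year) ifelse(is.na(year), NA_real_, year - a)
  bc_t <- off(cohort$bc1_year)
  oc_t <- off(cohort$oc_year)
  death_t <- off(cohort$death_year)
  brrm_t <- off(round(cohort$brrm_age - cohort$age_entry))
  rrso_t <- off(round(cohort$rrso_age - cohort$age_entry))
  keep <- function(x) ifelse(!is.na(x) & x >= 0, x, NA_real_)
  death_cens <- ifelse(is.na(death_t), Inf, pmax(death_t, 0))
  curves <- bind_rows(
    km_curve(keep(bc_t), pmin(death_cens, ifelse(is.na(oc_t), Inf, oc_t)),
             t_max) %>% mutate(outcome = "breast"),
    km_curve(keep(oc_t), pmin(death_cens, ifelse(is.na(bc_t), Inf, bc_t)),
             t_max) %>% mutate(outcome = "ovary"),
    km_curve(keep(brrm_t), pmin(death_cens,
                                ifelse(is.na(bc_t), Inf, bc_t)), t_max) %>%
      mutate(outcome = "brrm"),
    km_curve(keep(rrso_t), pmin(death_cens,
                                ifelse(is.na(oc_t), Inf, oc_t)), t_max) %>%
      mutate(outcome = "rrso"))
  structure(curves[, c("outcome", "time", "at_risk", "events", "cum_inc")],
            class = c("hboc_curves", class(tibble())))
}

#' @importFrom ggplot2 autoplot ggplot aes geom_step facet_wrap labs
#' @export
autoplot.hboc_curves <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$cum_inc,
                     colour = .data$outcome)) +
    geom_step() +
    labs(x = "Years since proband diagnosis", y = "Cumulative incidence",
         colour = NULL)
}

#' Cross-scenario outcome table
#'
#' Builds the per-scenario summary rows: proband counts, carrier prevalence
#' by gene, diagnostic and predictive test counts and percentages,
#' secondary ovarian cancer in carrier probands, relatives alive per
#' carrier proband at diagnosis, and life expectancy / anchored life-years
#' with confidence intervals for the carrier families.
#'
#' @param sims Named list of `hboc_sim` objects (names = scenario labels);
#'   runs must share the population.
#' @param max_dx_age Proband diagnosis age cut-off (default 80).
#' @return Tibble of class `hboc_outcomes`: `group`, `outcome`, `scenario`,
#'   `value`, and a formatted `label`.
#' @export
summary_report <- function(sims, max_dx_age = 80) {
  if (inherits(sims, "hboc_sim")) sims <- list(sims)
  if (is.null(names(sims)) || any(names(sims) == "")) {
    names(sims) <- vapply(sims, function(s) s$scenario$scenario, character(1))
  }
  rows <- purrr::imap_dfr(sims, function(sim, nm) {
    co <- select_cohort(sim, max_dx_age)
    pro <- co$probands
    rel <- co$relatives
    n_pro <- nrow(pro)
    pct <- function(n, d) ifelse(d > 0, 100 * n / d, NA_real_)
    add <- function(group, outcome, value, label = NULL) {
      tibble(group = group, outcome = outcome, scenario = nm, value = value,
             label = if (is.null(label)) format(value) else label)
    }
    carrier_pro <- pro %>% filter(.data$gene > 0L)
    hr_pro <- pro %>%
      filter(.data$gene %in% match(HIGH_RISK_GENES, GENES))
    hr_fams <- hr_pro$fam
    rel_hr <- rel %>% filter(.data$fam %in% hr_fams)
    alive_cnt <- rel_hr %>%
      filter(.data$alive_at_anchor) %>% count(.data$fam)
    mean_rel <- ifelse(nrow(hr_pro) > 0,
                       sum(alive_cnt$n) / nrow(hr_pro), NA_real_)
    sec_oc <- sum(!is.na(carrier_pro$oc_year) &
                    carrier_pro$oc_year > carrier_pro$bc1_year)
    n_diag <- sum(pro$panel_tested & pro$panel_year >= pro$bc1_year, na.rm = TRUE)
    n_pred_pro <- sum(pro$pred_tested)
    out <- bind_rows(
      add("probands", "total", n_pro),
      add("probands", "mean_dx_age", mean(pro$bc1_age)),
      purrr::map_dfr(HIGH_RISK_GENES, function(g) {
        ng <- sum(pro$gene == match(g, GENES))
        add("probands", paste0("prevalence_", g), ng,
            sprintf("%d (%.2f%%)", ng, pct(ng, n_pro)))
      }),
      add("probands", "prevalence_total", nrow(carrier_pro),
          sprintf("%d (%.2f%%)", nrow(carrier_pro),
                  pct(nrow(carrier_pro), n_pro))),
      add("probands", "diagnostic_tests", n_diag,
          sprintf("%d (%.2f%%)", n_diag, pct(n_diag, n_pro))),
      add("probands", "predictive_tests", n_pred_pro,
          sprintf("%d (%.2f%%)", n_pred_pro, pct(n_pred_pro, n_pro))),
      add("probands", "secondary_ovarian_in_carriers", sec_oc,
          sprintf("%d (%.2f%%)", sec_oc, pct(sec_oc, nrow(carrier_pro)))),
      add("relatives_of_carrier_probands", "alive_at_dx_per_proband", mean_rel)
    )
    rel_f <- rel_hr %>%
      filter(.data$female, .data$alive_at_anchor, .data$unaffected_at_anchor)
    if (nrow(rel_f)) {
      n_diag_r <- sum(rel_hr$panel_tested)
      n_pred_r <- sum(rel_hr$pred_tested)
      out <- bind_rows(out,
        add("relatives_of_carrier_probands", "diagnostic_tests", n_diag_r,
            sprintf("%d (%.2f%%)", n_diag_r, pct(n_diag_r, nrow(rel_hr)))),
        add("relatives_of_carrier_probands", "predictive_tests", n_pred_r,
            sprintf("%d (%.2f%%)", n_pred_r, pct(n_pred_r, nrow(rel_hr)))))
      lm_all <- life_metrics(rel_f, rel_f$anchor_year)
      out <- bind_rows(out,
        add("unaffected_female_relatives", "n_per_proband",
            nrow(rel_f) / max(1, nrow(hr_pro))),
        add("unaffected_female_relatives", "life_expectancy",
            lm_all$life_expectancy,
            sprintf("%.3f (%.3f, %.3f)", lm_all$life_expectancy,
                    lm_all$le_lo, lm_all$le_hi)),
        add("unaffected_female_relatives", "anchored_life_years",
            lm_all$anchored_life_years,
            sprintf("%.3f (%.3f, %.3f)", lm_all$anchored_life_years,
                    lm_all$aly_lo, lm_all$aly_hi)))
      rel_c <- rel_f %>% filter(.data$gene > 0L)
      if (nrow(rel_c)) {
        dr <- detection_rate(rel_c)
        lm_c <- life_metrics(rel_c, rel_c$anchor_year)
        out <- bind_rows(out,
          add("carrier_relatives", "n_per_proband",
              nrow(rel_c) / max(1, nrow(hr_pro))),
          add("carrier_relatives", "detection_rate", dr$rate,
              sprintf("%.1f%%", 100 * dr$rate)),
          add("carrier_relatives", "life_expectancy", lm_c$life_expectancy,
              sprintf("%.3f (%.3f, %.3f)", lm_c$life_expectancy,
                      lm_c$le_lo, lm_c$le_hi)),
          add("carrier_relatives", "anchored_life_years",
              lm_c$anchored_life_years,
              sprintf("%.3f (%.3f, %.3f)", lm_c$anchored_life_years,
                      lm_c$aly_lo, lm_c$aly_hi)))
      }
    }
    out
  })
  structure(rows, class = c("hboc_outcomes", class(tibble())))
}

#' Write an outcome table to CSV and markdown
#'
#' @param x An `hboc_outcomes` tibble from [summary_report()].
#' @param path Base path (without extension); writes `<path>.csv` and
#'   `<path>.md`.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(x, path) {
  wide <- x %>%
    select("group", "outcome", "scenario", "label") %>%
    tidyr::pivot_wider(names_from = "scenario", values_from = "label")
  readr::write_csv(wide, paste0(path, ".csv"))
  scen <- setdiff(names(wide), c("group", "outcome"))
  lines <- c(paste0("| group | outcome | ", paste(scen, collapse = " | "), " |"),
             paste0("|", paste(rep("---", 2 + length(scen)), collapse = "|"), "|"),
             vapply(seq_len(nrow(wide)), function(i) {
               paste0("| ", wide$group[i], " | ", wide$outcome[i], " | ",
                      paste(unlist(wide[i, scen]), collapse = " | "), " |")
             }, character(1)))
  writeLines(lines, paste0(path, ".md"))
  invisible(path)
}
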