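# Simulation engine: yearly cycles over the generated population under a
# scenario configuration.
#
# Cycle order (declared, audit-visible): ageing -> births (dynamic) ->
# event-time draws for other-cause death -> cancer onset/progression ->
# screening -> symptomatic/screen diagnosis (competing with death by
# within-year event times) -> referral + diagnostic testing (same year as
# diagnosis) -> family-knowledge update + predictive testing -> risk-pathway
# update + risk-reducing surgery -> death resolution -> exit at age 100.

SCENARIOS <- c("no_testing", "current_practice", "optimised_referral",
               "test_all_breast")

#' Build a genetic-testing scenario configuration
#'
#' The four scenarios: `no_testing` (no genetic testing, no high-risk
#' management); `current_practice` (referral odds model, MBS eligibility,
#' high-risk panel); `optimised_referral` (referral probability 1 for all
#' cancer cases, eligibility unchanged); `test_all_breast` (additionally,
#' genetic testing for every breast cancer diagnosed before 80). Population
#' breast screening is active in all scenarios; extended-panel genes are
#' excluded unless `panel = "extended"` is requested explicitly.
#'
#' @param name One of `r paste(SCENARIOS, collapse=", ")`.
#' @param panel `"high_risk"` or `"extended"`.
#' @param dynamic_population Should children be born during the simulation?
#' @param horizon Number of yearly cycles, 1-160.
#' @param seed Integer seed for the simulation draw streams.
#' @param disable_relative_diagnostic_testing Sensitivity toggle: relatives
#'   never receive diagnostic sequencing (family variants can only be found
#'   in probands).
#' @param force_full_predictive_uptake Sensitivity toggle: every eligible
#'   relative tests in the year the family variant is identified.
#' @param uptake_multiplier Scales every testing-uptake probability
#'   (diagnostic and predictive); 0 collapses scenarios 2-4 onto scenario 1.
#' @return A `hboc_scenario` list.
#' @export
build_scenario <- function(name, panel = "high_risk",
                           dynamic_population = TRUE, horizon = 160L,
                           seed = 1L,
                           disable_relative_diagnostic_testing = FALSE,
                           force_full_predictive_uptake = FALSE,
                           uptake_multiplier = 1) {
  if (!name %in% SCENARIOS) {
    abort(paste0("unknown scenario '", name, "'; expected one of: ",
                 paste(SCENARIOS, collapse = ", ")))
  }
  if (!panel %in% c("high_risk", "extended")) abort("unknown panel")
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L || horizon > 160L) {
    abort("config error: horizon must be in [1, 160]")
  }
  structure(list(
    scenario = name, panel = panel,
    dynamic_population = isTRUE(dynamic_population),
    horizon = horizon, seed = as.integer(seed),
    disable_relative_diagnostic_testing = isTRUE(disable_relative_diagnostic_testing),
    force_full_predictive_uptake = isTRUE(force_full_predictive_uptake),
    uptake_multiplier = uptake_multiplier
  ), class = "hboc_scenario")
}

#' @export
print.hboc_scenario <- function(x, ...) {
  cat("<hboc_scenario>", x$scenario, "| panel:", x$panel,
      "| dynamic:", x$dynamic_population, "| horizon:", x$horizon,
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Run the microsimulation
#'
#' Simulates every person in `population` forward in yearly cycles under the
#' scenario until death or age 100 (or the horizon). All stochastic draws
#' come from counter-based streams keyed by (seed, person, process, year),
#' so results are reproducible and scenario comparisons with the same
#' population and seed are paired by common random numbers.
#'
#' @param population An `hboc_population` from [generate_population()].
#' @param sc An `hboc_scenario` from [build_scenario()].
#' @param p An `hboc_params` object.
#' @param progress Print a line every 20 cycles to stderr.
#' @return An `hboc_sim` object: list with `population` (final person table
#'   as a tibble), `scenario`, `n_cycles`, `fam_gene`, `fam_year`.
#' @export
run_simulation <- function(population, sc, p = default_parameters(),
                           progress = FALSE) {
  stopifnot(inherits(sc, "hboc_scenario"))
  pp <- prepare_params(p)
  st <- init_state(population, sc, pp)
  for (t in seq_len(sc$horizon)) {
    run_cycle_impl(st, t, sc, pp)
    if (progress && t %% 20L == 0L) {
      message("cycle ", t, ": ", sum(st$alive), " alive")
    }
    if (!any(st$alive) && !any(st$unborn)) break
  }
  finalize_sim(st, sc)
}

#' Advance one yearly cycle
#'
#' Applies the fixed within-cycle process order to a simulation state; used
#' by [run_simulation()]. Exposed for stepwise runs in analyses and tests.
#'
#' @param state State environment from `init_state()` (internal structure).
#' @param t Cycle index (1-based).
#' @param sc Scenario configuration.
#' @param p An `hboc_params` object or prepared parameters.
#' @return The state, invisibly (modified in place).
#' @export
run_cycle <- function(state, t, sc, p = default_parameters()) {
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  run_cycle_impl(state, t, sc, pp)
  invisible(state)
}

#' Initialise simulation state from a population
#'
#' @param population An `hboc_population`.
#' @param sc An `hboc_scenario`.
#' @param p Parameters (an `hboc_params` or prepared parameters).
#' @return A state environment.
#' @export
init_state <- function(population, sc, p = default_parameters()) {
  pp <- if (inherits(p, "hboc_params")) prepare_params(p) else p
  pop <- population
  n <- nrow(pop)
  st <- new.env(parent = emptyenv())
  st$pop <- pop
  st$n <- n
  st$seed <- sc$seed
  st$id <- pop$id
  st$fam <- pop$fam
  st$rel <- pop$rel
  st$female <- pop$female
  st$member <- pop$member
  st$gene <- pop$gene
  st$age_entry <- pop$age_entry
  st$age <- pop$age_entry

  st$alive <- pop$alive0 == "alive"
  st$born <- pop$alive0 %in% c("alive", "deceased")
  st$unborn <- pop$alive0 == "unborn" & sc$dynamic_population
  st$death_age <- pop$death_age0
  st$death_cause <- ifelse(is.na(pop$death_cause0), NA_character_,
                           ifelse(pop$death_cause0 == "cancer",
                                  "cancer", pop$death_cause0))
  st$death_year <- rep(NA_integer_, n)

  st$mult_b <- exp(pp$ln_b * pop$zb) / pp$norm_b
  st$mult_o <- exp(pp$ln_o * pop$zo) / pp$norm_o
  st$soj_ml <- pp$soj_meanlog[pop$gene + 1L]
  st$soj_sd <- pp$soj_sdlog[pop$gene + 1L]

  st$n_bc <- (!is.na(pop$bc1_age0)) + (!is.na(pop$bc2_age0))
  st$bc1_age <- pop$bc1_age0
  st$bc1_stage <- pop$bc1_stage0
  st$bc1_mode <- ifelse(is.na(pop$bc1_age0), NA_character_, "baseline")
  st$bc1_subtype <- rep(NA_character_, n)
  st$bc1_year <- rep(NA_integer_, n)
  st$bc2_age <- pop$bc2_age0
  st$bc2_year <- rep(NA_integer_, n)
  st$oc_age <- pop$oc_age0
  st$oc_stage <- pop$oc_stage0
  st$oc_hist <- pop$oc_hist0
  st$oc_year <- rep(NA_integer_, n)
  st$bc_pre <- pop$bc_pre0
  st$bc_onset <- pop$bc_onset0
  st$bc_expiry <- pop$bc_expiry0

  st$brrm_age <- rep(NA_real_, n)
  st$crrm_age <- rep(NA_real_, n)
  st$rrso_age <- rep(NA_real_, n)

  # population screening start (age, or Inf for never-screeners)
  u <- cr_unif(sc$seed, st$id, PROC$screen_start, 0L)
  nv <- pp$const$never_screen
  start <- rep(Inf, n)
  starters <- st$female & u >= nv
  u2 <- (u[starters] - nv) / (1 - nv)
  start[starters] <- draw_cat(u2, pp$start_cdf, pp$start_age)
  st$pop_start <- start
  st$next_screen <- pmax(start, floor(st$age_entry) + 1)
  st$n_screens <- integer(n)
  st$pathway <- integer(n)          # 0 population, 1 moderate, 2 high risk
  st$hr_next <- rep(Inf, n)

  st$referred_year <- rep(NA_integer_, n)
  st$panel_tested <- rep(FALSE, n)
  st$panel_year <- rep(NA_integer_, n)
  st$panel_kind <- rep(NA_character_, n)
  st$pred_tested <- rep(FALSE, n)
  st$pred_year <- rep(NA_integer_, n)
  st$result_pos <- rep(FALSE, n)
  st$result_neg_fam <- rep(FALSE, n)   # observed negative for family variant
  st$pos_year <- rep(NA_integer_, n)

  nfam <- max(pop$fam)
  st$nfam <- nfam
  st$fam_gene <- integer(nfam)
  st$fam_year <- rep(NA_integer_, nfam)
  st$poss <- rep(TRUE, n)          # could carry the family variant
  st$pred_deg <- rep(2L, n)        # degree to nearest known carrier

  ford <- order(pop$fam)
  st$ford <- ford
  st$fptr <- c(0L, cumsum(tabulate(pop$fam, nbins = nfam)))

  st$pairs <- build_relative_pairs(pop)
  st$affected <- !is.na(st$bc1_age) | !is.na(st$oc_age)
  st$exited <- rep(FALSE, n)
  # cascade accounting over the five years after a family variant is
  # identified. The at-risk denominator is fixed at identification: eligible
  # relatives alive, cancer-unaffected and aged 18+ that year. Yearly
  # candidate risk sets/tests are also kept by offset 0..4 for curves.
  st$casc_risk <- numeric(5)
  st$casc_tests <- numeric(5)
  st$casc_member <- rep(FALSE, n)
  st$casc_denom <- 0
  st$casc_tests5_member <- 0
  st$casc_tests5_all <- 0
  # cohort-restricted yearly risk sets and tests for the product-limit
  # uptake estimate (members leave the risk set at death, panel testing or
  # loss of eligibility)
  st$casc_mrisk <- numeric(5)
  st$casc_mtests <- numeric(5)
  st
}

fam_rows <- function(st, f) {
  st$ford[(st$fptr[f] + 1L):st$fptr[f + 1L]]
}

# probability of dying next cycle, using exactly the draws cycle t+1 will use
peek_death_next_year <- function(st, k, t, pp) {
  a <- pmin(as.integer(floor(st$age[k])), 100L)
  q <- pp$qx[cbind(ifelse(st$female[k], 1L, 2L), a + 1L)]
  die <- cr_unif(st$seed, st$id[k], PROC$ocd, t + 1L) < q
  has_bc <- !is.na(st$bc1_age[k])
  if (any(has_bc)) {
    i <- which(has_bc)
    pk <- excess_death_prob(1L, st$bc1_stage[k[i]], a[i] - st$bc1_age[k[i]],
                            st$bc1_age[k[i]], NULL, pp)
    die[i] <- die[i] | cr_unif(st$seed, st$id[k[i]], PROC$cdeath_bc, t + 1L) < pk
  }
  has_oc <- !is.na(st$oc_age[k])
  if (any(has_oc)) {
    i <- which(has_oc)
    pk <- excess_death_prob(2L, st$oc_stage[k[i]], a[i] - st$oc_age[k[i]],
                            st$oc_age[k[i]], st$oc_hist[k[i]], pp)
    die[i] <- die[i] | cr_unif(st$seed, st$id[k[i]], PROC$cdeath_oc, t + 1L) < pk
  }
  die
}

# refresh carrier-possibility and degree-to-carrier for one family
refresh_family_knowledge <- function(st, f) {
  rows <- fam_rows(st, f)
  gidx <- st$fam_gene[f]
  if (gidx == 0L) return(invisible())
  pos_rows <- rows[st$result_pos[rows]]
  neg_rows <- rows[st$result_neg_fam[rows]]
  ft <- tibble(id = st$id[rows],
               mother = st$pop$mother[rows],
               father = st$pop$father[rows])
  st$poss[rows] <- carrier_possible(ft, st$id[pos_rows], st$id[neg_rows])
  deg <- rep(2L, length(rows))
  if (length(pos_rows)) {
    for (q in pos_rows) {
      a <- st$pairs$ptr[q] + 1L; b <- st$pairs$ptr[q + 1L]
      if (b < a) next
      j <- st$pairs$jj[a:b]; d <- st$pairs$dd[a:b]
      lj <- match(j, rows)
      ok <- !is.na(lj)
      deg[lj[ok]] <- pmin(deg[lj[ok]], d[ok])
    }
  }
  st$pred_deg[rows] <- deg
  invisible()
}

run_cycle_impl <- function(st, t, sc, pp) {
  seed <- st$seed
  testing_on <- sc$scenario != "no_testing"

  ## 1. ageing
  st$age <- st$age_entry + t

  ## 2. births (dynamic population)
  if (any(st$unborn)) {
    due <- which(st$unborn & st$age >= 0 & st$age < 1)
    if (length(due)) {
      mo <- st$pop$mother[due]
      ok <- !is.na(mo) & (st$alive[mo] | !st$member[mo])
      st$alive[due[ok]] <- TRUE
      st$born[due[ok]] <- TRUE
      st$unborn[due] <- FALSE     # birth either happens now or never
    }
  }

  act <- which(st$alive & st$age <= 100)
  if (!length(act)) return(invisible())
  ids <- st$id[act]
  # start-of-year attained age: hazards h(a) govern the year [a, a+1)
  a_int <- pmax(0L, as.integer(floor(st$age[act])) - 1L)

  ## 3. other-cause death times
  q <- pp$qx[cbind(ifelse(st$female[act], 1L, 2L), pmin(a_int, 100L) + 1L)]
  u_oc <- cr_unif(seed, ids, PROC$ocd, t)
  t_other <- ifelse(u_oc < q, u_oc / pmax(q, 1e-300), Inf)

  ## cancer-specific deaths for cancers diagnosed in earlier cycles
  t_cbc <- rep(Inf, length(act))
  prev_bc <- !is.na(st$bc1_age[act]) & st$bc1_age[act] < st$age[act] - 1e-9
  if (any(prev_bc)) {
    i <- which(prev_bc)
    pk <- excess_death_prob(1L, st$bc1_stage[act[i]],
                            a_int[i] - st$bc1_age[act[i]],
                            st$bc1_age[act[i]], NULL, pp)
    uu <- cr_unif(seed, ids[i], PROC$cdeath_bc, t)
    hit <- uu < pk
    t_cbc[i[hit]] <- uu[hit] / pk[hit]
  }
  t_coc <- rep(Inf, length(act))
  prev_oc <- !is.na(st$oc_age[act]) & st$oc_age[act] < st$age[act] - 1e-9
  if (any(prev_oc)) {
    i <- which(prev_oc)
    pk <- excess_death_prob(2L, st$oc_stage[act[i]],
                            a_int[i] - st$oc_age[act[i]],
                            st$oc_age[act[i]], st$oc_hist[act[i]], pp)
    uu <- cr_unif(seed, ids[i], PROC$cdeath_oc, t)
    hit <- uu < pk
    t_coc[i[hit]] <- uu[hit] / pk[hit]
  }
  t_death <- pmin(t_other, t_cbc, t_coc)

  fem <- st$female[act]

  ## 4. cancer onset
  h_b <- pp$haz_breast[cbind(st$gene[act] + 1L, pmin(a_int, 100L) + 1L)] *
    st$mult_b[act]
  post_brrm <- !is.na(st$brrm_age[act])
  h_b[post_brrm] <- h_b[post_brrm] * pp$const$brrm_multiplier
  post_rrso <- !is.na(st$rrso_age[act])
  h_b[post_rrso] <- h_b[post_rrso] * pp$const$rrso_breast_multiplier
  second <- st$n_bc[act] == 1L
  can_onset <- fem & !st$bc_pre[act] & st$n_bc[act] < 2L &
    !(second & !is.na(st$crrm_age[act]))
  p_on <- ifelse(can_onset, 1 - exp(-h_b), 0)
  u_on <- numeric(length(act))
  i1 <- which(!second); i2 <- which(second)
  if (length(i1)) u_on[i1] <- cr_unif(seed, ids[i1], PROC$bc_onset, t)
  if (length(i2)) u_on[i2] <- cr_unif(seed, ids[i2], PROC$bc_onset2, t)
  onset <- u_on < p_on
  if (any(onset)) {
    k <- act[onset]
    u_s <- cr_unif(seed, st$id[k], PROC$sojourn, t)
    soj <- stats::qlnorm(u_s, st$soj_ml[k], st$soj_sd[k])
    st$bc_pre[k] <- TRUE
    st$bc_onset[k] <- st$age[k] - 1 + u_on[onset] / p_on[onset]
    st$bc_expiry[k] <- st$bc_onset[k] + soj
  }

  h_o <- pp$haz_ovary[cbind(st$gene[act] + 1L, pmin(a_int, 100L) + 1L)] *
    st$mult_o[act]
  h_o[post_rrso] <- h_o[post_rrso] * pp$const$rrso_ovary_multiplier
  can_oc <- fem & is.na(st$oc_age[act])
  p_oc <- ifelse(can_oc, 1 - exp(-h_o), 0)
  u_ocn <- cr_unif(seed, ids, PROC$oc_onset, t)
  oc_hit <- u_ocn < p_oc
  t_dxo <- ifelse(oc_hit, u_ocn / pmax(p_oc, 1e-300), Inf)

  ## 5. screening
  scr_detect <- rep(FALSE, length(act))
  # population pathway
  pop_due <- fem & st$pathway[act] == 0L & st$n_bc[act] == 0L &
    is.na(st$brrm_age[act]) &
    a_int >= st$next_screen[act] &
    a_int <= pp$const$pop_screen_stop
  if (any(pop_due)) {
    i <- which(pop_due)
    k <- act[i]
    sens <- pp$mam_sens[pmin(a_int[i], 100L) + 1L]
    has_pre <- st$bc_pre[k]
    u_r <- cr_unif(seed, ids[i], PROC$screen_res, t)
    det <- has_pre & u_r < sens
    scr_detect[i[det]] <- TRUE
    st$n_screens[k] <- st$n_screens[k] + 1L
    u_d <- cr_unif(seed, ids[i], PROC$screen_att, t)
    extra <- draw_cat(u_d, pp$delay_pop$cdf, pp$delay_pop$years)
    st$next_screen[k] <- a_int[i] + pp$const$pop_screen_interval + extra
  }
  # high/moderate risk surveillance
  hr_due <- fem & st$pathway[act] > 0L & st$n_bc[act] == 0L &
    is.na(st$brrm_age[act]) & a_int >= st$hr_next[act]
  if (any(hr_due)) {
    i <- which(hr_due)
    k <- act[i]
    aa <- pmin(a_int[i], 100L)
    high <- st$pathway[k] == 2L
    mam_ok <- ifelse(high,
                     aa >= pp$const$hr_mammo_lo & aa <= pp$const$hr_mammo_hi,
                     aa >= pp$const$mod_mammo_lo & aa <= pp$const$mod_mammo_hi)
    mri_ok <- high & aa >= pp$const$hr_mri_lo & aa <= pp$const$hr_mri_hi
    sens <- 1 - (1 - ifelse(mam_ok, pp$mam_sens[aa + 1L], 0)) *
      (1 - ifelse(mri_ok, pp$mri_sens[aa + 1L], 0))
    attend <- mam_ok | mri_ok
    u_r <- cr_unif(seed, ids[i], PROC$screen_res, t)
    det <- attend & st$bc_pre[k] & u_r < sens
    scr_detect[i[det]] <- TRUE
    st$n_screens[k[attend]] <- st$n_screens[k[attend]] + 1L
    u_d <- cr_unif(seed, ids[i], PROC$screen_att, t)
    extra <- draw_cat(u_d, pp$delay_hr_int$cdf, pp$delay_hr_int$years)
    st$hr_next[k] <- a_int[i] + pp$const$hr_screen_interval + extra
  }

  ## 6. breast/ovarian diagnoses, competing with death within the year
  t_dxb <- rep(Inf, length(act))
  sympt <- st$bc_pre[act] & !is.na(st$bc_expiry[act]) &
    st$bc_expiry[act] < st$age[act]
  t_dxb[sympt] <- pmax(0, st$bc_expiry[act][sympt] - (st$age[act][sympt] - 1))
  t_dxb[scr_detect] <- pmin(t_dxb[scr_detect], 0.5)
  mode_b <- ifelse(scr_detect, "screen", "symptomatic")

  new_bc <- which(t_dxb < t_death)
  if (length(new_bc)) {
    k <- act[new_bc]
    att <- sample_breast_attributes(st$id[k], st$gene[k],
                                    "symptomatic", t, seed, pp)
    # size/nodes drawn per detection mode
    if (any(mode_b[new_bc] == "screen")) {
      ks <- which(mode_b[new_bc] == "screen")
      atts <- sample_breast_attributes(st$id[k[ks]], st$gene[k[ks]],
                                       "screen", t, seed, pp)
      att$size[ks] <- atts$size; att$nodes[ks] <- atts$nodes
      att$met[ks] <- atts$met; att$stage[ks] <- atts$stage
      att$subtype[ks] <- atts$subtype; att$grade[ks] <- atts$grade
    }
    dx_age <- st$age[k] - 1 + t_dxb[new_bc]
    first <- st$n_bc[k] == 0L
    kf <- k[first]; kn <- k[!first]
    st$bc1_age[kf] <- dx_age[first]
    st$bc1_stage[kf] <- att$stage[first]
    st$bc1_mode[kf] <- mode_b[new_bc][first]
    st$bc1_subtype[kf] <- att$subtype[first]
    st$bc1_year[kf] <- t
    st$bc2_age[kn] <- dx_age[!first]
    st$bc2_year[kn] <- t
    st$n_bc[k] <- st$n_bc[k] + 1L
    st$bc_pre[k] <- FALSE
    st$bc_onset[k] <- NA_real_; st$bc_expiry[k] <- NA_real_
    st$affected[k] <- TRUE
    st$new_bc_rows <- k
    st$new_bc_grade <- att$grade
    st$new_bc_subtype <- att$subtype
  } else st$new_bc_rows <- integer(0)

  new_oc <- which(oc_hit & t_dxo < t_death)
  if (length(new_oc)) {
    k <- act[new_oc]
    dx_age <- st$age[k] - 1 + t_dxo[new_oc]
    att <- sample_ovarian_attributes(st$id[k], st$gene[k], dx_age, t, seed, pp)
    st$oc_age[k] <- dx_age
    st$oc_stage[k] <- att$stage
    st$oc_hist[k] <- att$histology
    st$oc_year[k] <- t
    st$affected[k] <- TRUE
    st$new_oc_rows <- k
    st$new_oc_grade <- att$grade
  } else st$new_oc_rows <- integer(0)

  ## 7. referral + diagnostic testing (same year as diagnosis)
  changed_fams <- integer(0)
  if (testing_on) {
    um <- sc$uptake_multiplier
    # breast referrals
    if (length(st$new_bc_rows)) {
      k <- st$new_bc_rows
      keep <- !(sc$disable_relative_diagnostic_testing & st$rel[k] != "proband")
      k <- k[keep]
      if (length(k)) {
        grade <- st$new_bc_grade[keep]
        subtype <- st$new_bc_subtype[keep]
        dx_age <- ifelse(!is.na(st$bc2_year[k]) & st$bc2_year[k] == t,
                         st$bc2_age[k], st$bc1_age[k])
        surv12 <- peek_death_next_year(st, k, t, pp)
        if (sc$scenario %in% c("optimised_referral", "test_all_breast")) {
          p_ref <- rep(1, length(k))
        } else {
          p_ref <- referral_probability("breast", dx_age,
                                        high_grade = grade == 3L,
                                        subtype = subtype,
                                        survival_lt12m = surv12, p = pp)
        }
        refd <- cr_unif(st$seed, st$id[k], PROC$refer, t) < p_ref
        st$referred_year[k[refd & is.na(st$referred_year[k])]] <- t
        n_aff <- count_flagged_relatives(st$pairs, k, st$affected)
        elig <- is_test_eligible("breast", dx_age, subtype = subtype,
                                 grade = grade, bilateral = st$n_bc[k] >= 2L,
                                 n_affected = n_aff)
        offer <- refd & elig & !st$panel_tested[k]
        p_upt <- rep(pp$uptake_breast * um, length(k))
        if (sc$scenario == "test_all_breast") {
          univ <- dx_age < 80 & !st$panel_tested[k]
          offer <- offer | univ
          p_upt[univ] <- 1 * um
        }
        tk <- offer & cr_unif(st$seed, st$id[k], PROC$uptake, t) < p_upt
        changed_fams <- c(changed_fams,
                          do_diagnostic_tests(st, k[tk], t, sc))
      }
    }
    # ovarian referrals
    if (length(st$new_oc_rows)) {
      k <- st$new_oc_rows
      keep <- !(sc$disable_relative_diagnostic_testing & st$rel[k] != "proband")
      k <- k[keep]
      if (length(k)) {
        grade <- st$new_oc_grade[keep]
        dx_age <- st$oc_age[k]
        surv12 <- peek_death_next_year(st, k, t, pp)
        if (sc$scenario %in% c("optimised_referral", "test_all_breast")) {
          p_ref <- rep(1, length(k))
        } else {
          p_ref <- referral_probability("ovary", dx_age,
                                        high_grade = grade >= 2L,
                                        histology = st$oc_hist[k],
                                        survival_lt12m = surv12,
                                        prior_breast = st$n_bc[k] > 0L, p = pp)
        }
        refd <- cr_unif(st$seed, st$id[k], PROC$refer, t) < p_ref
        st$referred_year[k[refd & is.na(st$referred_year[k])]] <- t
        n_aff <- count_flagged_relatives(st$pairs, k, st$affected)
        elig <- is_test_eligible("ovary", dx_age, grade = grade,
                                 histology = st$oc_hist[k],
                                 n_affected = n_aff)
        tk <- refd & elig & !st$panel_tested[k] &
          cr_unif(st$seed, st$id[k], PROC$uptake, t) < pp$uptake_ovary * um
        changed_fams <- c(changed_fams,
                          do_diagnostic_tests(st, k[tk], t, sc))
      }
    }
  }

  ## 8. family-knowledge update + predictive testing
  if (length(changed_fams)) {
    for (f in unique(changed_fams)) refresh_family_knowledge(st, f)
  }
  if (testing_on) {
    kf <- which(st$fam_gene > 0L & st$fam_year <= t)
    if (length(kf)) {
      cand_l <- lapply(kf, function(f) fam_rows(st, f))
      cand <- unlist(cand_l, use.names = FALSE)
      fam_of <- rep(kf, lengths(cand_l))
      ok <- st$alive[cand] & st$member[cand] & !st$panel_tested[cand] &
        !st$pred_tested[cand] & !st$result_pos[cand] & st$poss[cand]
      cand <- cand[ok]; fam_of <- fam_of[ok]
      if (length(cand)) {
        yrs <- t - st$fam_year[fam_of]
        in5 <- yrs >= 0L & yrs <= 4L
        if (any(in5)) {
          st$casc_risk <- st$casc_risk + tabulate(yrs[in5] + 1L, nbins = 5L)
        }
        new0 <- which(yrs == 0L & st$age[cand] - 1 >= 18 & !st$affected[cand])
        if (length(new0)) {
          st$casc_member[cand[new0]] <- TRUE
          st$casc_denom <- st$casc_denom + length(new0)
        }
        memb <- st$casc_member[cand] & in5
        if (any(memb)) {
          st$casc_mrisk <- st$casc_mrisk + tabulate(yrs[memb] + 1L, nbins = 5L)
        }
        if (sc$force_full_predictive_uptake) {
          pr <- rep(1, length(cand))
        } else {
          ab <- pred_age_band(floor(st$age[cand]) - 1)
          tb <- pred_time_band(yrs)
          pr <- pp$pred_uptake[cbind(st$pred_deg[cand], ab, tb)] *
            ifelse(st$female[cand], 1, pp$male_rr) * sc$uptake_multiplier
        }
        tk <- cr_unif(st$seed, st$id[cand], PROC$predictive, t) < pr
        if (any(tk & in5)) {
          st$casc_tests <- st$casc_tests +
            tabulate(yrs[tk & in5] + 1L, nbins = 5L)
          st$casc_tests5_all <- st$casc_tests5_all + sum(tk & in5)
          st$casc_tests5_member <- st$casc_tests5_member +
            sum(tk & in5 & st$casc_member[cand])
          st$casc_mtests <- st$casc_mtests +
            tabulate(yrs[tk & in5 & st$casc_member[cand]] + 1L, nbins = 5L)
        }
        if (any(tk)) {
          kk <- cand[tk]; ff <- fam_of[tk]
          st$pred_tested[kk] <- TRUE
          st$pred_year[kk] <- t
          pos <- st$gene[kk] == st$fam_gene[ff]
          st$result_pos[kk[pos]] <- TRUE
          st$pos_year[kk[pos]] <- ifelse(is.na(st$pos_year[kk[pos]]), t,
                                         st$pos_year[kk[pos]])
          st$result_neg_fam[kk[!pos]] <- TRUE
          for (f in unique(ff)) refresh_family_knowledge(st, f)
        }
      }
    }
  }

  ## 9. risk pathway + risk-reducing surgery
  if (testing_on) {
    pos_new <- which(st$result_pos & st$pathway == 0L & st$alive & st$female)
    if (length(pos_new)) {
      high <- GENES[st$gene[pos_new]] %in% HIGH_RISK_GENES
      st$pathway[pos_new] <- ifelse(high, 2L, 1L)
      u_d <- cr_unif(st$seed, st$id[pos_new], PROC$hr_start, t)
      delay <- draw_cat(u_d, pp$delay_hr_start$cdf, pp$delay_hr_start$years)
      lo <- ifelse(high, pp$const$hr_mammo_lo, pp$const$mod_mammo_lo)
      st$hr_next[pos_new] <- pmax(lo, st$age[pos_new] - 1) + delay
    }
    # BRRM / RRSO for known carriers without the relevant cancer history
    kb <- which(st$alive & st$female & st$result_pos & is.na(st$brrm_age) &
                  st$n_bc == 0L & st$age <= 100)
    if (length(kb)) {
      pr <- pp$brrm_uptake[cbind(st$gene[kb],
                                 pmax(0L, pmin(floor(st$age[kb]) - 1, 100L)) + 1L)]
      tk <- cr_unif(st$seed, st$id[kb], PROC$brrm, t) < pr
      kbb <- kb[tk]
      st$brrm_age[kbb] <- st$age[kbb] - 1
      st$bc_pre[kbb] <- FALSE      # preclinical disease removed at surgery
      st$bc_onset[kbb] <- NA_real_; st$bc_expiry[kbb] <- NA_real_
    }
    ko <- which(st$alive & st$female & st$result_pos & is.na(st$rrso_age) &
                  is.na(st$oc_age) & st$age <= 100)
    if (length(ko)) {
      pr <- pp$rrso_uptake[cbind(st$gene[ko],
                                 pmax(0L, pmin(floor(st$age[ko]) - 1, 100L)) + 1L)]
      tk <- cr_unif(st$seed, st$id[ko], PROC$rrso, t) < pr
      st$rrso_age[ko[tk]] <- st$age[ko[tk]] - 1
    }
  }
  # CRRM at unilateral breast-cancer diagnosis (all scenarios; uptake higher
  # for known carriers)
  if (length(st$new_bc_rows)) {
    k <- st$new_bc_rows
    k <- k[st$n_bc[k] == 1L & is.na(st$crrm_age[k]) & is.na(st$brrm_age[k])]
    if (length(k)) {
      pr <- ifelse(st$result_pos[k], pp$const$crrm_uptake_carrier,
                   pp$const$crrm_uptake_noncarrier)
      tk <- cr_unif(st$seed, st$id[k], PROC$crrm, t) < pr
      kk <- k[tk]
      st$crrm_age[kk] <- st$age[kk] - 1
      st$bc_pre[kk] <- FALSE
      st$bc_onset[kk] <- NA_real_; st$bc_expiry[kk] <- NA_real_
    }
  }

  ## 10. death resolution
  dies <- which(is.finite(t_death))
  if (length(dies)) {
    k <- act[dies]
    st$alive[k] <- FALSE
    st$death_age[k] <- st$age[k] - 1 + t_death[dies]
    st$death_year[k] <- t
    st$death_cause[k] <- ifelse(t_other[dies] <= pmin(t_cbc[dies], t_coc[dies]),
                                "other",
                                ifelse(t_cbc[dies] <= t_coc[dies],
                                       "cancer_breast", "cancer_ovary"))
  }

  ## 11. exit at age 100
  ex <- which(st$alive & st$age >= 100)
  if (length(ex)) {
    st$alive[ex] <- FALSE
    st$exited[ex] <- TRUE
    st$death_age[ex] <- 100
    st$death_year[ex] <- t
    st$death_cause[ex] <- "exit"
  }
  invisible()
}

# perform diagnostic panel tests for rows k; returns families with new
# knowledge
do_diagnostic_tests <- function(st, k, t, sc) {
  if (!length(k)) return(integer(0))
  st$panel_tested[k] <- TRUE
  st$panel_year[k] <- t
  st$panel_kind[k] <- sc$panel
  on_panel <- if (sc$panel == "extended") st$gene[k] > 0L else
    st$gene[k] > 0L & GENES[pmax(st$gene[k], 1L)] %in% HIGH_RISK_GENES
  pos <- k[on_panel]
  st$result_pos[pos] <- TRUE
  st$pos_year[pos] <- ifelse(is.na(st$pos_year[pos]), t, st$pos_year[pos])
  changed <- integer(0)
  if (length(pos)) {
    for (r in pos) {
      f <- st$fam[r]
      if (st$fam_gene[f] == 0L) {
        st$fam_gene[f] <- st$gene[r]
        st$fam_year[f] <- t
        changed <- c(changed, f)
      } else if (st$fam_gene[f] == st$gene[r]) {
        changed <- c(changed, f)
      }
      # a different-gene second variant does not start a second cascade
    }
  }
  # panel-tested negatives exclude the family gene when the panel covers it
  neg <- k[!on_panel]
  if (length(neg)) {
    f <- st$fam[neg]
    covered <- st$fam_gene[f] > 0L &
      (sc$panel == "extended" |
         GENES[pmax(st$fam_gene[f], 1L)] %in% HIGH_RISK_GENES)
    st$result_neg_fam[neg[covered]] <- TRUE
    changed <- c(changed, f[covered])
  }
  changed
}

finalize_sim <- function(st, sc) {
  popn <- tibble(
    id = st$id, fam = st$fam, rel = st$rel, female = st$female,
    member = st$member, gene = st$gene, age_entry = st$age_entry,
    alive = st$alive, exited = st$exited,
    death_age = st$death_age, death_year = st$death_year,
    death_cause = st$death_cause,
    never_born = st$pop$never_born,
    unborn_left = st$unborn,
    bc1_age = st$bc1_age, bc1_year = st$bc1_year, bc1_stage = st$bc1_stage,
    bc1_mode = st$bc1_mode, bc1_subtype = st$bc1_subtype,
    bc2_age = st$bc2_age, bc2_year = st$bc2_year,
    oc_age = st$oc_age, oc_year = st$oc_year, oc_stage = st$oc_stage,
    oc_hist = st$oc_hist,
    referred_year = st$referred_year,
    panel_tested = st$panel_tested, panel_year = st$panel_year,
    pred_tested = st$pred_tested, pred_year = st$pred_year,
    result_pos = st$result_pos, pos_year = st$pos_year,
    brrm_age = st$brrm_age, crrm_age = st$crrm_age, rrso_age = st$rrso_age,
    pop_start = st$pop_start, n_screens = st$n_screens,
    pathway = st$pathway, born = st$born, cascade_at_risk = st$casc_member
  )
  structure(list(population = popn,
                 fam_gene = st$fam_gene,
                 fam_year = st$fam_year,
                 cascade = list(risk = st$casc_risk, tests = st$casc_tests,
                                denom = st$casc_denom,
                                tests5_member = st$casc_tests5_member,
                                tests5_all = st$casc_tests5_all,
                                member_risk = st$casc_mrisk,
                                member_tests = st$casc_mtests),
                 scenario = sc,
                 n_cycles = sc$horizon),
            class = "hboc_sim")
}

#' @export
print.hboc_sim <- function(x, ...) {
  po <- x$population
  cat("<hboc_sim>", x$scenario$scenario, "|", nrow(po), "persons |",
      sum(!is.na(po$bc1_age)), "breast ca |", sum(!is.na(po$oc_age)),
      "ovarian ca |", sum(po$panel_tested), "panel tests |",
      sum(po$pred_tested), "predictive tests\n")
  invisible(x)
}

#' Long-format event log of a simulation
#'
#' @param x An `hboc_sim`.
#' @param ... Unused.
#' @return Tibble with columns `id`, `fam`, `year`, `event`, `age`; one row
#'   per event (diagnoses, tests, surgeries, deaths), sorted by person and
#'   year. Death is terminal per person.
#' @export
tidy.hboc_sim <- function(x, ...) {
  po <- x$population
  ev <- list(
    po %>% filter(!is.na(.data$bc1_year)) %>%
      mutate(year = .data$bc1_year, event = "breast_diagnosis",
             age = .data$bc1_age),
    po %>% filter(!is.na(.data$bc2_year)) %>%
      mutate(year = .data$bc2_year, event = "breast_diagnosis2",
             age = .data$bc2_age),
    po %>% filter(!is.na(.data$oc_year)) %>%
      mutate(year = .data$oc_year, event = "ovarian_diagnosis",
             age = .data$oc_age),
    po %>% filter(!is.na(.data$referred_year)) %>%
      mutate(year = .data$referred_year, event = "referral",
             age = .data$age_entry + .data$referred_year),
    po %>% filter(.data$panel_tested) %>%
      mutate(year = .data$panel_year, event = "diagnostic_test",
             age = .data$age_entry + .data$panel_year),
    po %>% filter(.data$pred_tested) %>%
      mutate(year = .data$pred_year, event = "predictive_test",
             age = .data$age_entry + .data$pred_year),
    po %>% filter(!is.na(.data$brrm_age)) %>%
      mutate(year = round(.data$brrm_age - .data$age_entry), event = "brrm",
             age = .data$brrm_age),
    po %>% filter(!is.na(.data$crrm_age)) %>%
      mutate(year = round(.data$crrm_age - .data$age_entry), event = "crrm",
             age = .data$crrm_age),
    po %>% filter(!is.na(.data$rrso_age)) %>%
      mutate(year = round(.data$rrso_age - .data$age_entry), event = "rrso",
             age = .data$rrso_age),
    po %>% filter(!is.na(.data$death_year)) %>%
      mutate(year = .data$death_year,
             event = ifelse(.data$death_cause == "exit", "exit", "death"),
             age = .data$death_age)
  )
  bind_rows(lapply(ev, function(d) d[, c("id", "fam", "year", "event", "age")])) %>%
    arrange(.data$id, .data$year)
}

#' One-row summary of a simulation
#'
#' @param x An `hboc_sim`.
#' @param ... Unused.
#' @return One-row tibble with scenario, person and event counts.
#' @export
glance.hboc_sim <- function(x, ...) {
  po <- x$population
  tibble(
    scenario = x$scenario$scenario,
    n_persons = nrow(po),
    n_families = length(x$fam_gene),
    n_breast = sum(!is.na(po$bc1_age)),
    n_ovarian = sum(!is.na(po$oc_age)),
    n_panel_tests = sum(po$panel_tested),
    n_predictive_tests = sum(po$pred_tested),
    n_positive = sum(po$result_pos),
    n_brrm = sum(!is.na(po$brrm_age)),
    n_rrso = sum(!is.na(po$rrso_age)),
    n_variant_families = sum(x$fam_gene > 0L)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
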