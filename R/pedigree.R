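# Population generation: proband-centred families with first- and
# second-degree relatives, genotypes (monogenic + polygenic), and pre-entry
# cancer histories.
#
# Construction is vectorised across families. Every female (and male, via a
# paternal shift of the same schedule) receives a completed parity draw and
# maternal-age-at-birth draws; children whose birth falls after the proband's
# entry are created as "unborn" (negative age at entry) and activate during a
# dynamic-population run. Married-in co-parents are generated as non-members:
# they contribute genes but are excluded from family-size metrics.

#' Sample number of children from the age-specific parity CDFs
#'
#' Inverse-CDF draw from the parity distribution of the age group containing
#' `age` (number of children ever born by that age).
#'
#' @param age Age in years (vectorised).
#' @param p An `hboc_params` object.
#' @param u Optional uniforms in (0,1), one per age (injectable for testing);
#'   defaults to `runif()` draws.
#' @return Integer vector of child counts.
#' @export
sample_parity <- function(age, p, u = NULL) {
  stopifnot(all(age >= 0))
  if (is.null(u)) u <- runif(length(age))
  stopifnot(length(u) == length(age))
  grp <- cut(age, breaks = c(-1, 19, 24, 29, 34, 39, 44, Inf),
             labels = c("0-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45+"))
  out <- integer(length(age))
  for (g in levels(grp)) {
    i <- which(grp == g)
    if (!length(i)) next
    tab <- p$parity_age[p$parity_age$age_group == g, ]
    tab <- tab[order(tab$children), ]
    out[i] <- tab$children[findInterval(u[i], tab$cdf, left.open = TRUE) + 1L]
  }
  out
}

# completed-parity draw; cond_ge1 conditions on at least one child (used for
# the mothers/grandmothers whose existence of a child is given)
draw_completed_parity <- function(n, pp, cond_ge1 = FALSE) {
  cdf <- pp$parity_cdf
  u <- runif(n)
  if (cond_ge1) {
    # a degenerate all-zero parity distribution still implies the one child
    # whose existence is given
    if (cdf[1] >= 1) return(rep(1L, n))
    u <- pmin(cdf[1] + u * (1 - cdf[1]), 1 - 1e-12)
  }
  pp$parity_k[findInterval(u, cdf, left.open = TRUE) + 1L]
}

draw_maternal_age <- function(n, pp) {
  pp$mat_age[findInterval(runif(n), pp$mat_cdf, left.open = TRUE) + 1L]
}

draw_spouse_gap <- function(n, pp) {
  g <- round(rnorm(n, pp$const$spouse_gap_mean, pp$const$spouse_gap_sd))
  pmin(12, pmax(-6, g))
}

#' Generate a proband-centred population of families
#'
#' Builds `n_families` family units: a cancer-free female proband, two
#' parents, four grandparents, and siblings, piblings (aunts/uncles),
#' children, niblings (nieces/nephews) and grandchildren drawn from the
#' parity distributions. Assigns sex, ages, monogenic and polygenic
#' genotypes, and simulates each relative's pre-entry history (cancers and
#' deaths) up to their age at entry.
#'
#' @param n_families Number of families.
#' @param p An `hboc_params` object (default [default_parameters()]).
#' @param proband_age_group Two-element numeric, inclusive age range the
#'   proband's entry age is drawn from uniformly; within 20-59.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param proband_gene Optional gene name: condition the generation on the
#'   proband carrying that variant (the carrier lineage is traced back
#'   through one parent and grandparent; all other transmissions are
#'   ordinary Mendelian draws). Used for carrier-conditioned analyses.
#' @param baseline_history If `FALSE`, skip pre-entry history simulation
#'   (all relatives enter alive and cancer-free).
#' @return A tibble of persons (class `hboc_population`), one row each, with
#'   pedigree pointers (`mother`, `father` as row ids), genotype and
#'   pre-entry history columns.
#' @export
generate_population <- function(n_families, p = default_parameters(),
                                proband_age_group = c(20, 24), seed = 1L,
                                proband_gene = NULL,
                                baseline_history = TRUE) {
  stopifnot(n_families >= 1, length(proband_age_group) == 2,
            proband_age_group[1] >= 20, proband_age_group[2] <= 59,
            proband_age_group[1] <= proband_age_group[2])
  if (!is.null(proband_gene)) stopifnot(proband_gene %in% GENES)
  pp <- prepare_params(p)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- as.integer(n_families)

  ## ---- structure ----
  A <- sample(proband_age_group[1]:proband_age_group[2], n, replace = TRUE)
  mother_age <- A + draw_maternal_age(n, pp)
  father_age <- mother_age + draw_spouse_gap(n, pp)
  mgm_age <- mother_age + draw_maternal_age(n, pp)
  mgf_age <- mgm_age + draw_spouse_gap(n, pp)
  pgm_age <- father_age + draw_maternal_age(n, pp)
  pgf_age <- pgm_age + draw_spouse_gap(n, pp)

  K_m <- draw_completed_parity(n, pp, cond_ge1 = TRUE)   # mother incl. proband
  S <- K_m - 1L                                          # siblings
  K_mg <- draw_completed_parity(n, pp, cond_ge1 = TRUE)  # maternal grandmother
  K_pg <- draw_completed_parity(n, pp, cond_ge1 = TRUE)  # paternal grandmother
  P_m <- K_mg - 1L; P_p <- K_pg - 1L                     # piblings
  K_p <- draw_completed_parity(n, pp)                    # proband's children

  shift <- pp$const$paternal_shift

  blocks <- list()
  nid <- 0L
  new_block <- function(fam, rel, female, mother, father, age) {
    k <- length(fam)
    ids <- nid + seq_len(k)
    nid <<- nid + k
    blocks[[length(blocks) + 1L]] <<- list(
      id = as.integer(ids), fam = as.integer(fam), rel = rel,
      female = female, mother = as.integer(mother), father = as.integer(father),
      age = as.numeric(age))
    as.integer(ids)
  }

  id_mgm <- new_block(1:n, "grandmother", rep(TRUE, n), NA, NA, mgm_age)
  id_mgf <- new_block(1:n, "grandfather", rep(FALSE, n), NA, NA, mgf_age)
  id_pgm <- new_block(1:n, "grandmother", rep(TRUE, n), NA, NA, pgm_age)
  id_pgf <- new_block(1:n, "grandfather", rep(FALSE, n), NA, NA, pgf_age)
  id_mo <- new_block(1:n, "mother", rep(TRUE, n), id_mgm, id_mgf, mother_age)
  id_fa <- new_block(1:n, "father", rep(FALSE, n), id_pgm, id_pgf, father_age)

  # piblings: other children of each grandmother couple
  fam_pm <- rep(1:n, P_m)
  pib_m <- new_block(fam_pm, "pibling", runif(length(fam_pm)) < 0.5,
                     id_mgm[fam_pm], id_mgf[fam_pm],
                     mgm_age[fam_pm] - draw_maternal_age(length(fam_pm), pp))
  fam_pp <- rep(1:n, P_p)
  pib_p <- new_block(fam_pp, "pibling", runif(length(fam_pp)) < 0.5,
                     id_pgm[fam_pp], id_pgf[fam_pp],
                     pgm_age[fam_pp] - draw_maternal_age(length(fam_pp), pp))

  id_pro <- new_block(1:n, "proband", rep(TRUE, n), id_mo, id_fa, A)

  fam_s <- rep(1:n, S)
  sib_female <- runif(length(fam_s)) < 0.5
  id_sib <- new_block(fam_s, "sibling", sib_female, id_mo[fam_s], id_fa[fam_s],
                      mother_age[fam_s] - draw_maternal_age(length(fam_s), pp))
  sib_age <- blocks[[length(blocks)]]$age

  # offspring counts for siblings and for the proband's children
  K_s <- draw_completed_parity(length(fam_s), pp)

  fam_c <- rep(1:n, K_p)
  # child ages relative to proband's own birth schedule
  child_age <- A[fam_c] - draw_maternal_age(length(fam_c), pp)
  child_female <- runif(length(fam_c)) < 0.5
  K_c <- draw_completed_parity(length(fam_c), pp)

  # married-in co-parents (non-members): for proband (if children), siblings
  # with children, and the proband's children with children
  sp_pro <- which(K_p > 0)                       # family index
  sp_sib <- which(K_s > 0)                       # sibling row index
  sp_chl <- which(K_c > 0)                       # child row index
  id_sp_pro <- rep(NA_integer_, n)
  id_sp_pro[sp_pro] <- new_block(sp_pro, "spouse", rep(FALSE, length(sp_pro)),
                                 NA, NA, A[sp_pro] + draw_spouse_gap(length(sp_pro), pp))
  id_sp_sib <- rep(NA_integer_, length(fam_s))
  if (length(sp_sib)) {
    id_sp_sib[sp_sib] <- new_block(fam_s[sp_sib], "spouse", !sib_female[sp_sib],
                                   NA, NA,
                                   sib_age[sp_sib] + ifelse(sib_female[sp_sib], 1, -1) *
                                     draw_spouse_gap(length(sp_sib), pp))
  }
  id_sp_chl <- rep(NA_integer_, length(fam_c))
  if (length(sp_chl)) {
    id_sp_chl[sp_chl] <- new_block(fam_c[sp_chl], "spouse", !child_female[sp_chl],
                                   NA, NA,
                                   child_age[sp_chl] + ifelse(child_female[sp_chl], 1, -1) *
                                     draw_spouse_gap(length(sp_chl), pp))
  }

  id_chl <- new_block(fam_c, "child", child_female,
                      ifelse(child_female | TRUE, NA, NA), NA, child_age)
  # set child parents: mother is the female of (proband, spouse)
  blocks[[length(blocks)]]$mother <- id_pro[fam_c]          # proband is female
  blocks[[length(blocks)]]$father <- id_sp_pro[fam_c]

  fam_nib <- rep(fam_s, K_s)
  sib_of_nib <- rep(seq_along(fam_s), K_s)
  nib_birth <- draw_maternal_age(length(fam_nib), pp) +
    ifelse(rep(sib_female, K_s), 0, shift)
  id_nib <- new_block(fam_nib, "nibling", runif(length(fam_nib)) < 0.5,
                      NA, NA, sib_age[sib_of_nib] - nib_birth)
  blocks[[length(blocks)]]$mother <- ifelse(sib_female[sib_of_nib],
                                            id_sib[sib_of_nib], id_sp_sib[sib_of_nib])
  blocks[[length(blocks)]]$father <- ifelse(sib_female[sib_of_nib],
                                            id_sp_sib[sib_of_nib], id_sib[sib_of_nib])

  fam_gc <- rep(fam_c, K_c)
  chl_of_gc <- rep(seq_along(fam_c), K_c)
  gc_birth <- draw_maternal_age(length(fam_gc), pp) +
    ifelse(rep(child_female, K_c), 0, shift)
  id_gc <- new_block(fam_gc, "grandchild", runif(length(fam_gc)) < 0.5,
                     NA, NA, child_age[chl_of_gc] - gc_birth)
  blocks[[length(blocks)]]$mother <- ifelse(child_female[chl_of_gc],
                                            id_chl[chl_of_gc], id_sp_chl[chl_of_gc])
  blocks[[length(blocks)]]$father <- ifelse(child_female[chl_of_gc],
                                            id_sp_chl[chl_of_gc], id_chl[chl_of_gc])

  pop <- list(
    id = unlist(lapply(blocks, `[[`, "id")),
    fam = unlist(lapply(blocks, `[[`, "fam")),
    rel = unlist(lapply(blocks, function(b) rep_len(b$rel, length(b$id)))),
    female = unlist(lapply(blocks, `[[`, "female")),
    mother = unlist(lapply(blocks, function(b) rep_len(b$mother, length(b$id)))),
    father = unlist(lapply(blocks, function(b) rep_len(b$father, length(b$id)))),
    age_entry = unlist(lapply(blocks, `[[`, "age"))
  )
  ord <- order(pop$id)
  pop <- lapply(pop, `[`, ord)
  pop$member <- pop$rel != "spouse"

  pop <- as_tibble(pop)[, c("id", "fam", "rel", "female", "member",
                            "mother", "father", "age_entry")]

  pop <- assign_genotypes_impl(pop, pp, proband_gene = proband_gene)

  if (baseline_history) {
    pop <- assign_baseline_history_impl(pop, pp, seed = seed)
  } else {
    npop <- nrow(pop)
    pop$never_born <- FALSE
    pop$alive0 <- ifelse(pop$age_entry < 0, "unborn", "alive")
    pop$death_age0 <- rep(NA_real_, npop)
    pop$death_cause0 <- rep(NA_character_, npop)
    pop$bc1_age0 <- rep(NA_real_, npop); pop$bc1_stage0 <- rep(NA_integer_, npop)
    pop$bc2_age0 <- rep(NA_real_, npop)
    pop$oc_age0 <- rep(NA_real_, npop); pop$oc_stage0 <- rep(NA_integer_, npop)
    pop$oc_hist0 <- rep(NA_character_, npop)
    pop$bc_pre0 <- rep(FALSE, npop)
    pop$bc_onset0 <- rep(NA_real_, npop); pop$bc_expiry0 <- rep(NA_real_, npop)
  }

  structure(pop,
            class = c("hboc_population", class(tibble())),
            seed = as.integer(seed),
            proband_age_group = proband_age_group)
}

#' Generate a single family
#'
#' Convenience wrapper around [generate_population()] for one family.
#'
#' @inheritParams generate_population
#' @return A one-family `hboc_population` tibble.
#' @export
generate_family <- function(p = default_parameters(),
                            proband_age_group = c(20, 24), seed = 1L, ...) {
  generate_population(1L, p = p, proband_age_group = proband_age_group,
                      seed = seed, ...)
}

# ---- genotypes -------------------------------------------------------------

#' Assign genotypes to a generated population
#'
#' Founders (grandparents and married-in co-parents) receive a single P/LP
#' variant from the population prevalences and independent standard-normal
#' polygenic scores; descendants inherit Mendelianly (transmission 1/2 from
#' a heterozygous carrier parent, no de novo events) and polygenic scores by
#' the infinitesimal model: child z = midparent mean + N(0, 1/2), preserving
#' unit marginal variance.
#'
#' @param pop An `hboc_population` tibble (structure columns present).
#' @param p An `hboc_params` object.
#' @param seed Integer seed.
#' @return `pop` with `gene` (0 = none, otherwise index into [hboc_genes()]),
#'   `zb`, `zo` columns replaced.
#' @export
assign_genotypes <- function(pop, p = default_parameters(), seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  assign_genotypes_impl(pop, prepare_params(p))
}

assign_genotypes_impl <- function(pop, pp, proband_gene = NULL) {
  npop <- nrow(pop)
  gene <- integer(npop)
  zb <- numeric(npop); zo <- numeric(npop)
  founder <- is.na(pop$mother) & is.na(pop$father)

  cumprev <- cumsum(pp$prev)
  nf <- sum(founder)
  u <- runif(nf)
  gf0 <- findInterval(u, c(0, cumprev), left.open = TRUE)  # 1..8 within prev, 9 = none
  gf0[gf0 > length(cumprev)] <- 0L
  gene[founder] <- as.integer(gf0)
  rho <- pp$const$polygenic_corr
  zb[founder] <- rnorm(nf)
  zo[founder] <- rho * zb[founder] + sqrt(1 - rho^2) * rnorm(nf)

  # forced carrier lineage for carrier-conditioned generation
  forced <- rep(FALSE, npop)
  if (!is.null(proband_gene)) {
    gidx <- match(proband_gene, GENES)
    pro <- which(pop$rel == "proband")
    parent <- ifelse(runif(length(pro)) < 0.5, pop$mother[pro], pop$father[pro])
    gp <- ifelse(runif(length(pro)) < 0.5, pop$mother[parent], pop$father[parent])
    forced[pro] <- TRUE; forced[parent] <- TRUE; forced[gp] <- TRUE
    gene[gp] <- gidx
  }

  # process non-founders by pedigree depth so each vectorised pass sees
  # fully assigned parents
  depth <- generation_depth(pop)
  for (d in sort(unique(depth[!founder]))) {
    r <- which(depth == d & !founder)
    m <- pop$mother[r]; f <- pop$father[r]
    um <- runif(length(r)); uf <- runif(length(r)); ut <- runif(length(r))
    gm <- gene[m]; gf <- gene[f]
    tm <- gm > 0L & um < 0.5
    tf <- gf > 0L & uf < 0.5
    gr <- integer(length(r))
    gr[tf] <- gf[tf]
    gr[tm] <- gm[tm]
    both <- tm & tf
    gr[both] <- ifelse(ut[both] < 0.5, gm[both], gf[both])
    fr <- forced[r]
    if (any(fr)) {
      gr[fr] <- ifelse(forced[m[fr]], gene[m[fr]], gene[f[fr]])
    }
    gene[r] <- gr
    eps_b <- rnorm(length(r), sd = sqrt(0.5))
    eps_o <- rho * eps_b + sqrt(1 - rho^2) * rnorm(length(r), sd = sqrt(0.5))
    zb[r] <- (zb[m] + zb[f]) / 2 + eps_b
    zo[r] <- (zo[m] + zo[f]) / 2 + eps_o
  }
  pop$gene <- gene
  pop$zb <- zb
  pop$zo <- zo
  pop
}

# ---- baseline history ------------------------------------------------------

#' Simulate pre-entry cancer histories and vital status
#'
#' Replays each relative's life from birth to their age at entry under the
#' genotype-adjusted natural-history hazards and the lifetable, assigning
#' breast/ovarian cancer histories (detected symptomatically, detection mode
#' "baseline") and deaths with cause. Probands are cancer-free and alive at
#' entry by definition and are not simulated. Children whose mother died
#' before their birth are marked never-born and removed from play.
#'
#' @param pop An `hboc_population` with genotypes assigned.
#' @param p An `hboc_params` object.
#' @param seed Integer seed for the counter-based draws.
#' @return `pop` with baseline-history columns replaced.
#' @export
assign_baseline_history <- function(pop, p = default_parameters(), seed = 1L) {
  assign_baseline_history_impl(pop, prepare_params(p), seed)
}

assign_baseline_history_impl <- function(pop, pp, seed) {
  npop <- nrow(pop)
  id <- pop$id
  female <- pop$female
  gene <- pop$gene
  zb <- pop$zb; zo <- pop$zo
  age_entry <- pop$age_entry
  sim <- pop$member & pop$rel != "proband" & age_entry > 0

  alive <- rep(TRUE, npop)
  death_age <- rep(NA_real_, npop)
  death_cause <- rep(NA_character_, npop)
  n_bc <- integer(npop)
  bc1_age <- rep(NA_real_, npop); bc1_stage <- rep(NA_integer_, npop)
  bc2_age <- rep(NA_real_, npop)
  oc_age <- rep(NA_real_, npop); oc_stage <- rep(NA_integer_, npop)
  oc_hist <- rep(NA_character_, npop)
  bc_pre <- rep(FALSE, npop)
  bc_onset <- rep(NA_real_, npop); bc_expiry <- rep(NA_real_, npop)

  mult_b <- exp(pp$ln_b * zb) / pp$norm_b
  mult_o <- exp(pp$ln_o * zo) / pp$norm_o
  soj_ml <- pp$soj_meanlog[gene + 1L]
  soj_sd <- pp$soj_sdlog[gene + 1L]

  for (a in 0:100) {
    act <- which(sim & alive & a < age_entry)
    if (!length(act)) next
    yr <- a + BASE_YEAR_OFFSET
    ids <- id[act]

    # other-cause death
    q <- pp$qx[cbind(ifelse(female[act], 1L, 2L), a + 1L)]
    u_oc <- cr_unif(seed, ids, PROC$ocd, yr)
    die_other <- u_oc < q
    t_other <- ifelse(die_other, u_oc / pmax(q, 1e-300), Inf)

    fem <- female[act]

    # breast preclinical onset (first and contralateral second course)
    h_b <- pp$haz_breast[cbind(gene[act] + 1L, a + 1L)] * mult_b[act]
    can_onset <- fem & !bc_pre[act] & n_bc[act] < 2L
    p_on <- ifelse(can_onset, 1 - exp(-h_b), 0)
    proc_on <- ifelse(n_bc[act] == 0L, PROC$bc_onset, PROC$bc_onset2)
    u_on <- numeric(length(act))
    for (pc in unique(proc_on)) {
      k <- proc_on == pc
      u_on[k] <- cr_unif(seed, ids[k], pc, yr)
    }
    onset <- u_on < p_on
    if (any(onset)) {
      k <- act[onset]
      u_s <- cr_unif(seed, id[k], PROC$sojourn, yr)
      soj <- stats::qlnorm(u_s, soj_ml[k], soj_sd[k])
      bc_pre[k] <- TRUE
      bc_onset[k] <- a + u_on[onset] / p_on[onset]
      bc_expiry[k] <- bc_onset[k] + soj
    }

    # symptomatic diagnosis when sojourn expires (no screening pre-entry)
    dx_b <- bc_pre[act] & !is.na(bc_expiry[act]) & bc_expiry[act] < a + 1
    t_dxb <- ifelse(dx_b, pmax(0, bc_expiry[act] - a), Inf)

    # ovarian cancer (no preclinical phase)
    h_o <- pp$haz_ovary[cbind(gene[act] + 1L, a + 1L)] * mult_o[act]
    can_oc <- fem & is.na(oc_age[act])
    p_oc <- ifelse(can_oc, 1 - exp(-h_o), 0)
    u_ocn <- cr_unif(seed, ids, PROC$oc_onset, yr)
    dx_o <- u_ocn < p_oc
    t_dxo <- ifelse(dx_o, u_ocn / pmax(p_oc, 1e-300), Inf)

    # cancer-specific excess mortality for prevalent cancers
    t_cd <- rep(Inf, length(act))
    has_bc <- !is.na(bc1_age[act])
    if (any(has_bc)) {
      k <- which(has_bc)
      yrs <- a - bc1_age[act[k]]
      band <- ifelse(yrs < 5, 1L, ifelse(yrs < 10, 2L, 3L))
      rate <- pp$exc[cbind(1L, bc1_stage[act[k]], band)] *
        pp$age_mult(bc1_age[act[k]])
      pk <- 1 - exp(-rate)
      uu <- cr_unif(seed, ids[k], PROC$cdeath_bc, yr)
      hit <- uu < pk
      t_cd[k[hit]] <- pmin(t_cd[k[hit]], uu[hit] / pk[hit])
    }
    has_oc <- !is.na(oc_age[act])
    if (any(has_oc)) {
      k <- which(has_oc)
      yrs <- a - oc_age[act[k]]
      band <- ifelse(yrs < 5, 1L, ifelse(yrs < 10, 2L, 3L))
      rate <- pp$exc[cbind(2L, oc_stage[act[k]], band)] *
        pp$hist_mult[oc_hist[act[k]]] * pp$age_mult(oc_age[act[k]])
      pk <- 1 - exp(-rate)
      uu <- cr_unif(seed, ids[k], PROC$cdeath_oc, yr)
      hit <- uu < pk
      t_cd[k[hit]] <- pmin(t_cd[k[hit]], uu[hit] / pk[hit])
    }

    t_death <- pmin(t_other, t_cd)

    # diagnoses that precede death within the year
    do_dxb <- dx_b & t_dxb < t_death
    if (any(do_dxb)) {
      k <- act[do_dxb]
      rec <- sample_breast_attributes(id[k], gene[k], "baseline", yr, seed, pp)
      first <- n_bc[k] == 0L
      bc1_age[k[first]] <- a + t_dxb[do_dxb][first]
      bc1_stage[k[first]] <- rec$stage[first]
      bc2_age[k[!first]] <- a + t_dxb[do_dxb][!first]
      n_bc[k] <- n_bc[k] + 1L
      bc_pre[k] <- FALSE
      bc_onset[k] <- NA_real_; bc_expiry[k] <- NA_real_
    }
    do_dxo <- dx_o & t_dxo < t_death
    if (any(do_dxo)) {
      k <- act[do_dxo]
      rec <- sample_ovarian_attributes(id[k], gene[k], a + t_dxo[do_dxo],
                                       yr, seed, pp)
      oc_age[k] <- a + t_dxo[do_dxo]
      oc_stage[k] <- rec$stage
      oc_hist[k] <- rec$histology
    }

    dies <- is.finite(t_death)
    if (any(dies)) {
      k <- act[dies]
      alive[k] <- FALSE
      death_age[k] <- a + t_death[dies]
      death_cause[k] <- ifelse(t_other[dies] <= t_cd[dies], "other", "cancer")
    }
  }

  # anyone whose entry age exceeds the 100-year cap and who survived to 100
  over <- sim & alive & age_entry > 100
  alive[over] <- FALSE
  death_age[over] <- 100
  death_cause[over] <- "other"

  # births cancelled by the mother's earlier death (passes by pedigree depth)
  never <- rep(FALSE, npop)
  depth <- generation_depth(pop)
  for (d in sort(unique(depth[!is.na(pop$mother)]))) {
    r <- which(depth == d & !is.na(pop$mother))
    m <- pop$mother[r]
    mab <- age_entry[m] - age_entry[r]  # mother's age at this birth
    never[r] <- never[m] |
      (!is.na(death_age[m]) & death_age[m] < mab)
  }
  if (any(never)) {
    alive[never] <- FALSE
    death_age[never] <- NA_real_; death_cause[never] <- NA_character_
    bc1_age[never] <- NA_real_; bc1_stage[never] <- NA_integer_
    bc2_age[never] <- NA_real_
    oc_age[never] <- NA_real_; oc_stage[never] <- NA_integer_
    oc_hist[never] <- NA_character_
    bc_pre[never] <- FALSE; bc_onset[never] <- NA_real_; bc_expiry[never] <- NA_real_
  }

  pop$never_born <- never
  pop$alive0 <- dplyr::case_when(
    never ~ "never_born",
    age_entry < 0 ~ "unborn",
    alive ~ "alive",
    TRUE ~ "deceased")
  pop$death_age0 <- death_age
  pop$death_cause0 <- death_cause
  pop$bc1_age0 <- bc1_age; pop$bc1_stage0 <- bc1_stage
  pop$bc2_age0 <- bc2_age
  pop$oc_age0 <- oc_age; pop$oc_stage0 <- oc_stage; pop$oc_hist0 <- oc_hist
  pop$bc_pre0 <- bc_pre
  pop$bc_onset0 <- bc_onset; pop$bc_expiry0 <- bc_expiry
  pop
}

#' Family size summary
#'
#' Counts family members (proband plus first/second-degree relatives,
#' excluding married-in co-parents and never-born or not-yet-born persons).
#'
#' @param pop An `hboc_population`.
#' @return Tibble with one row per family: `fam`, `size`.
#' @export
family_sizes <- function(pop) {
  pop %>%
    filter(.data$member, !.data$never_born, .data$age_entry >= 0) %>%
    count(.data$fam, name = "size")
}

# ---- PED import/export -----------------------------------------------------

#' Export a population to PED format
#'
#' Writes whitespace-delimited PED columns (family, id, father, mother, sex,
#' phenotype; phenotype 2 = any breast/ovarian cancer history, 1 =
#' unaffected) plus a JSON sidecar `<path>.json` carrying the model-specific
#' fields, so that [import_pedigree()] reproduces the population.
#'
#' @param pop An `hboc_population`.
#' @param path Output PED file path.
#' @return `path`, invisibly.
#' @export
export_pedigree <- function(pop, path) {
  ped <- tibble(
    fam = pop$fam, id = pop$id,
    father = ifelse(is.na(pop$father), 0L, pop$father),
    mother = ifelse(is.na(pop$mother), 0L, pop$mother),
    sex = ifelse(pop$female, 2L, 1L),
    phenotype = ifelse(!is.na(pop$bc1_age0) | !is.na(pop$oc_age0), 2L, 1L))
  utils::write.table(ped, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  extra <- as.list(pop[, setdiff(names(pop), c("fam", "id", "father", "mother"))])
  extra$female <- NULL
  meta <- list(columns = extra,
               seed = attr(pop, "seed"),
               proband_age_group = attr(pop, "proband_age_group"))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA, null = "null",
                       auto_unbox = TRUE)
  invisible(path)
}

#' Import a population from PED format
#'
#' Reads a PED file written by [export_pedigree()] together with its JSON
#' sidecar; the round trip is lossless.
#'
#' @param path PED file path (sidecar expected at `<path>.json`).
#' @return An `hboc_population` tibble.
#' @export
import_pedigree <- function(path) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  lines <- readLines(path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf != 6)
  if (length(bad)) {
    abort(paste0("malformed PED line ", bad[1], ": expected 6 fields, got ",
                 nf[bad[1]]))
  }
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  suppressWarnings(num <- matrix(as.numeric(m), ncol = 6))
  if (any(is.na(num))) {
    abad <- which(rowSums(is.na(num)) > 0)[1]
    abort(paste0("malformed PED line ", abad, ": non-numeric field"))
  }
  if (anyDuplicated(num[, 2])) {
    d <- num[duplicated(num[, 2]), 2][1]
    abort(paste0("invalid pedigree: person ", d,
                 " recorded more than once (conflicting parent assignments)"))
  }
  ped <- tibble(
    fam = as.integer(num[, 1]), id = as.integer(num[, 2]),
    father = ifelse(num[, 3] == 0, NA_integer_, as.integer(num[, 3])),
    mother = ifelse(num[, 4] == 0, NA_integer_, as.integer(num[, 4])),
    female = num[, 5] == 2)
  side <- paste0(path, ".json")
  if (!file.exists(side)) abort(paste0("missing sidecar file: ", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  cols <- meta$columns
  out <- ped[, c("id", "fam")]
  out$rel <- cols$rel
  out$female <- ped$female
  out$member <- cols$member
  out$mother <- ped$mother
  out$father <- ped$father
  for (nm in setdiff(names(cols), c("rel", "member"))) out[[nm]] <- cols[[nm]]
  structure(as_tibble(out),
            class = c("hboc_population", class(tibble())),
            seed = meta$seed,
            proband_age_group = meta$proband_age_group)
}
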