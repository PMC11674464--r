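# shared fixtures: cached parameters and small builders

the_params <- default_parameters()

# hand-built trio population: n independent families, founder parents and
# one child, ready for assign_genotypes()
build_trios <- function(n) {
  tibble::tibble(
    id = seq_len(3L * n),
    fam = rep(seq_len(n), each = 3L),
    rel = rep(c("father", "mother", "child"), n),
    female = rep(c(FALSE, TRUE, TRUE), n),
    member = TRUE,
    mother = as.integer(ifelse(rep(c(FALSE, FALSE, TRUE), n),
                               3L * rep(seq_len(n), each = 3L) - 1L, NA)),
    father = as.integer(ifelse(rep(c(FALSE, FALSE, TRUE), n),
                               3L * rep(seq_len(n), each = 3L) - 2L, NA)),
    age_entry = rep(c(55, 53, 25), n))
}

# parameters with a single-gene founder prevalence, everything else default
with_prevalence <- function(p, prev_brca1) {
  p$genes$prevalence <- c(prev_brca1, rep(0, 7))
  p
}

# small random pedigree (structure columns only) for oracle comparisons
random_small_pedigree <- function(seed, max_members = 10) {
  p <- the_params
  p$parity_completed$cdf <- c(0.3, 0.65, 0.9, 1, 1, 1, 1, 1, 1)
  p$parity_age <- derive_parity_age(p$parity_completed, p$maternal_age)
  fam <- generate_family(p = p, proband_age_group = c(40, 44), seed = seed,
                         baseline_history = FALSE)
  fam[seq_len(min(nrow(fam), max_members)),
      c("id", "mother", "father", "gene", "rel", "female")]
}
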