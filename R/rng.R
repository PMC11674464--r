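#' Counter-based uniform draws
#'
#' Deterministic uniforms derived by hashing `(seed, id, process, year)`.
#' Used for every stochastic decision inside the yearly simulation cycle so
#' that runs with the same seed are reproducible and scenario comparisons are
#' paired person-by-person (common random numbers), regardless of which
#' events a scenario actually evaluates.
#'
#' @param seed Integer master seed.
#' @param id Integer vector of person identifiers.
#' @param process Integer process code (one draw stream per process).
#' @param year Integer simulation year (cycle index).
#' @return Numeric vector of uniforms in (0, 1), one per `id`.
#' @export
cr_unif <- function(seed, id, process, year) {
  cr_unif_cpp(as.double(seed), as.integer(id), as.integer(process),
              as.integer(year))
}

# standard-normal variant of the same stream
cr_norm <- function(seed, id, process, year) {
  qnorm(cr_unif(seed, id, process, year))
}
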