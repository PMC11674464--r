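# shared internal helpers

# pedigree depth: founders 0, child = 1 + max(parent depths); iterated
# vectorised passes (pedigrees here are at most a few generations deep)
generation_depth <- function(pop) {
  npop <- nrow(pop)
  founder <- is.na(pop$mother) & is.na(pop$father)
  depth <- ifelse(founder, 0L, NA_integer_)
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    dm <- depth[pop$mother[todo]]
    df <- depth[pop$father[todo]]
    ready <- !is.na(dm) & !is.na(df)
    if (!any(ready)) abort("pedigree contains a cycle or a dangling parent")
    depth[todo[ready]] <- pmax(dm[ready], df[ready]) + 1L
  }
  depth
}

# inverse-CDF categorical draw: cum is a cumulative-probability vector,
# levels the matching values; u uniforms
draw_cat <- function(u, cum, levels) {
  levels[findInterval(u, cum, left.open = TRUE) + 1L]
}

# predictive-uptake age band index: <18, 18-29, 30-49, 50-59, 60+
pred_age_band <- function(age) {
  findInterval(age, c(18, 30, 50, 60)) + 1L
}

# time-since-identification band: t<1 -> 1, 1<=t<=3 -> 2, t>3 -> 3
pred_time_band <- function(t) {
  ifelse(t < 1, 1L, ifelse(t <= 3, 2L, 3L))
}

# quiet optional-column access (tibbles warn on `$` for missing columns)
col_or <- function(df, nm, default = NULL) {
  if (nm %in% names(df)) df[[nm]] else default
}
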