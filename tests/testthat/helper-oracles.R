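# Fixture builders and independent oracles used across the suite.
# The oracles deliberately avoid the package's scoring/statistics code
# paths: item-by-item counting loops, the covariance-matrix identity for
# alpha, and bitmask enumeration with pairwise-counting U.

`%or%` <- function(a, b) if (is.null(a)) b else a

# Build a case note with the named items marked missing.
# `missing` is a named list: section name -> character vector of item ids
# (applied to every entry) or a list of per-entry id vectors.
audit_note <- function(instrument, note_id = "n1", missing = list(),
                       n_entries = NULL, na_sections = character()) {
  sections <- lapply(instrument$sections, function(s) {
    if (s$name %in% na_sections)
      return(section_assessment(list(), applicable = FALSE))
    k <- if (s$repeat_policy == "averaged_repeat")
      (n_entries %or% s$max_entries) else 1L
    miss <- missing[[s$name]]
    entries <- lapply(seq_len(k), function(i) {
      m <- if (is.list(miss)) (miss[[i]] %or% character()) else (miss %or% character())
      e <- stats::setNames(rep(TRUE, length(s$items)), names(s$items))
      e[m] <- FALSE
      e
    })
    section_assessment(entries)
  })
  names(sections) <- names(instrument$sections)
  case_note(note_id, sections)
}

# Independent item-counting scorer: walks every entry item by item.
oracle_series <- function(instrument, notes) {
  nms <- names(instrument$sections)
  per_sec <- stats::setNames(numeric(length(nms)), nms)
  per_note_total <- numeric(length(notes))
  denom <- 0
  for (j in seq_along(notes)) {
    note <- notes[[j]]
    for (nm in nms) {
      sa <- note$sections[[nm]]
      if (!sa$applicable) next
      spec <- instrument$sections[[nm]]
      tot <- 0
      for (e in sa$entries) {
        for (id in names(spec$items)) {
          if (!e[[id]]) tot <- tot + spec$items[[id]]$deduction
        }
      }
      if (spec$repeat_policy == "averaged_repeat") tot <- tot / length(sa$entries)
      per_sec[[nm]] <- per_sec[[nm]] + tot
      per_note_total[j] <- per_note_total[j] + tot
      denom <- denom + spec$max_points
    }
  }
  D <- sum(per_sec)
  list(section_totals = per_sec, D = D,
       per_note_total = per_note_total,
       percent = 100 * (denom - D) / denom)
}

# Cronbach's alpha via the covariance-matrix identity
# alpha = k/(k-1) * (1 - tr(C) / sum(C)).
oracle_alpha <- function(m) {
  C <- stats::var(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# Mean pairwise correlation by explicit double loop.
oracle_mean_r <- function(m) {
  k <- ncol(m)
  rs <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) rs <- c(rs, stats::cor(m[, i], m[, j]))
  }
  mean(rs)
}

# Exact Mann-Whitney p by bitmask enumeration of group assignments, with
# the pairwise-counting definition of U (ties count one half). Valid for
# n1 + n2 <= 16.
oracle_mwu <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  stopifnot(N <= 16)
  z <- c(x, y)
  u_pair <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U_obs <- u_pair(x, y)
  masks <- 0:(2^N - 1)
  bits <- sapply(0:(N - 1), function(b) bitwAnd(bitwShiftR(masks, b), 1L))
  keep <- which(rowSums(bits) == n1)
  Us <- vapply(keep, function(k) {
    idx <- which(bits[k, ] == 1L)
    u_pair(z[idx], z[-idx])
  }, numeric(1))
  mu <- n1 * n2 / 2
  eps <- 1e-8
  switch(alternative,
         two.sided = mean(abs(Us - mu) >= abs(U_obs - mu) - eps),
         less      = mean(Us <= U_obs + eps),
         greater   = mean(Us >= U_obs - eps))
}

# A random missingness profile + generated series for property tests.
random_series <- function(instrument, seed, n_notes = NULL) {
  set.seed(seed)
  if (is.null(n_notes)) n_notes <- sample(1:10, 1)
  p <- lapply(instrument$sections, function(s)
    stats::setNames(runif(length(s$items), 0, 0.8), names(s$items)))
  profile <- missingness_profile(
    instrument, p_missing = p,
    entry_weights = c(0.1, 0.2, 0.3, 0.4)[seq_len(
      max(vapply(instrument$sections, `[[`, integer(1), "max_entries")))])
  notes <- generate_series(instrument, profile, n_notes, seed = seed + 1L)
  list(profile = profile, notes = notes, n_notes = n_notes)
}
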