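# Audit-cycle comparison: Mann-Whitney U tests on per-note scores and
# per-section deductions between a pre-change and a post-change series.
# Audit deductions are heavily tied small numbers, so an exact permutation
# path that tolerates ties is provided alongside the tie-corrected normal
# approximation.

#' Mann-Whitney U test (exact or normal approximation)
#'
#' U is computed from rank sums with midranks for ties. For small samples
#' (`n1 + n2 <= exact_limit`) the p-value is exact, by full enumeration of
#' all `choose(n1 + n2, n1)` group assignments of the observed ranks —
#' valid with or without ties. Larger samples use the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction. The
#' two-sided exact p is the permutation probability of a U at least as far
#' from `n1 * n2 / 2` as the observed one.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (direction of `x` relative to `y`).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   default `NULL` chooses exact when `n1 + n2 <= exact_limit`.
#' @param exact_limit Sample-size bound for the default exact path.
#' @return An object of class `mwu_test`: `U` (for the first sample), `p`,
#'   `method` (`"exact"` or `"normal-approximation"`), `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact = NULL, exact_limit = 20L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop_validation("both samples must be non-empty")
  if (anyNA(x) || anyNA(y))
    stop_validation("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- if (is.null(exact)) N <= exact_limit else isTRUE(exact)
  if (use_exact) {
    p <- mwu_exact_p(r, n1, U, alternative)
    method <- "exact"
  } else {
    p <- mwu_normal_p(r, n1, U, alternative)
    method <- "normal-approximation"
  }
  structure(list(U = U, p = p, method = method, n1 = n1, n2 = n2,
                 alternative = alternative),
            class = "mwu_test")
}

# Exact permutation distribution of U over all group assignments of the
# observed (mid)ranks. Ranks are multiples of 0.5, so a small epsilon
# makes the >= / <= comparisons safe.
mwu_exact_p <- function(r, n1, U, alternative) {
  N <- length(r)
  idx <- utils::combn(N, n1)
  Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * (N - n1) / 2
  eps <- 1e-8
  switch(alternative,
         two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
         less      = mean(Us <= U + eps),
         greater   = mean(Us >= U - eps))
}

# Normal approximation with tie-corrected variance and 0.5 continuity
# correction.
mwu_normal_p <- function(r, n1, U, alternative) {
  N <- length(r)
  n2 <- N - n1
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)  # all observations tied: no evidence either way
  sigma <- sqrt(sigma2)
  switch(alternative,
         two.sided = min(1, 2 * pnorm(-(max(abs(U - mu) - 0.5, 0)) / sigma)),
         less      = pnorm((U - mu + 0.5) / sigma),
         greater   = pnorm(-(U - mu - 0.5) / sigma))
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s)\nU = %g (n1 = %d, n2 = %d), p = %.4g\n",
              x$method, x$alternative, x$U, x$n1, x$n2, x$p))
  invisible(x)
}

#' Compare pre- and post-change audit series
#'
#' Runs a two-sided Mann-Whitney U test per instrument section on the
#' per-note section deductions, plus overall rows for per-note total
#' deductions and per-note percentage scores. Both series must carry
#' per-note data (i.e. come from [score_series()], not
#' [series_from_totals()]) and be scored under the same instrument. No
#' multiple-testing correction is applied across the section tests.
#'
#' @param pre,post `series_score` objects for the two audit cycles.
#' @param exact_limit Passed to [mann_whitney_u()].
#' @return An object of class `audit_comparison`: a data frame with
#'   columns `field`, `pre_deductions`, `post_deductions`, `U`, `p`,
#'   `method`.
#' @export
compare_series <- function(pre, post, exact_limit = 20L) {
  stopifnot(inherits(pre, "series_score"), inherits(post, "series_score"))
  if (is.null(pre$per_note) || is.null(post$per_note))
    stop_validation("compare_series needs per-note data; series built from section totals cannot be compared")
  if (!identical(pre$instrument$name, post$instrument$name) ||
      !identical(names(pre$instrument$sections), names(post$instrument$sections)))
    stop_validation("both series must be scored under the same instrument")
  sections <- names(pre$instrument$sections)
  one_row <- function(field, a, b, pre_ded, post_ded) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    t <- mann_whitney_u(a, b, exact_limit = exact_limit)
    data.frame(field = field, pre_deductions = pre_ded,
               post_deductions = post_ded, U = t$U, p = t$p,
               method = t$method, stringsAsFactors = FALSE)
  }
  rows <- lapply(sections, function(nm)
    one_row(nm, pre$per_note[, nm], post$per_note[, nm],
            pre$section_totals[[nm]], post$section_totals[[nm]]))
  pre_totals <- vapply(pre$note_scores, `[[`, numeric(1), "total")
  post_totals <- vapply(post$note_scores, `[[`, numeric(1), "total")
  rows <- c(rows, list(
    one_row("Total deductions", pre_totals, post_totals,
            pre$total_deductions, post$total_deductions),
    one_row("Score", vapply(pre$note_scores, `[[`, numeric(1), "percent"),
            vapply(post$note_scores, `[[`, numeric(1), "percent"),
            pre$percent, post$percent)))
  structure(do.call(rbind, rows), class = c("audit_comparison", "data.frame"))
}

#' @export
print.audit_comparison <- function(x, ...) {
  cat(render_report(x, format = "text"))
  invisible(x)
}
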