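# Inter-rater reliability over a complete notes x raters score matrix,
# as in a validation design where several doctors independently score the
# same small set of notes.

#' Build a rater score matrix
#'
#' @param values Numeric notes x raters matrix of per-note scores (points
#'   or percentages, used consistently). Complete design: no missing cells,
#'   at least 2 notes and 2 raters.
#' @param note_ids,rater_ids Optional identifiers; default to dimnames or
#'   `note1...`/`rater1...`.
#' @return A numeric matrix of class `rater_matrix`.
#' @export
rater_matrix <- function(values, note_ids = NULL, rater_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop_validation("rater matrix must be numeric")
  if (anyNA(values))
    stop_validation("rater matrix must be complete (no missing cells)")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop_validation("rater matrix needs at least 2 notes and 2 raters (got %d x %d)",
                    nrow(values), ncol(values))
  rownames(values) <- note_ids %||% rownames(values) %||%
    sprintf("note%d", seq_len(nrow(values)))
  colnames(values) <- rater_ids %||% colnames(values) %||%
    sprintf("rater%d", seq_len(ncol(values)))
  structure(values, class = c("rater_matrix", class(values)))
}

as_rater_matrix <- function(m) {
  if (inherits(m, "rater_matrix")) m else rater_matrix(m)
}

#' Cronbach's alpha across raters
#'
#' Treats raters as the "items" of a consistency analysis over notes:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` with `k` raters,
#' `var_i` the sample variance (n-1 denominator) of rater i's scores
#' across notes, and `var_total` the sample variance of the per-note score
#' sums. Alpha is invariant under jointly shifting or positively rescaling
#' all raters' scores, so points and percentages give identical values.
#'
#' @param matrix A [rater_matrix()] (or coercible matrix).
#' @return Alpha (dimensionless, at most 1).
#' @export
cronbach_alpha <- function(matrix) {
  m <- as_rater_matrix(matrix)
  k <- ncol(m)
  s2_total <- var(rowSums(m))
  if (s2_total <= 0)
    stop_stat("total-score variance is zero: alpha is undefined for this matrix")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / s2_total)
}

#' Mean inter-rater correlation
#'
#' Arithmetic mean of the Pearson correlations over all `k(k-1)/2` rater
#' pairs. Every rater must show variation across notes for the pairwise
#' correlations to exist.
#'
#' @param matrix A [rater_matrix()] (or coercible matrix).
#' @return Mean pairwise Pearson r, in `[-1, 1]`.
#' @export
mean_interitem_correlation <- function(matrix) {
  m <- as_rater_matrix(matrix)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop_stat("rater(s) with zero variance across notes: %s",
              toString(colnames(m)[sds == 0]))
  cm <- cor(m)
  mean(cm[upper.tri(cm)])
}

#' Standardised alpha from a mean inter-rater correlation
#'
#' The Spearman-Brown style closed form `k * r / (1 + (k - 1) * r)`. It
#' coincides with [cronbach_alpha()] whenever all raters have equal sample
#' variance.
#'
#' @param r_bar Mean pairwise correlation.
#' @param k Number of raters.
#' @return Standardised alpha.
#' @export
standardised_alpha <- function(r_bar, k) {
  k * r_bar / (1 + (k - 1) * r_bar)
}

#' Summarise inter-rater reliability
#'
#' @param matrix A [rater_matrix()].
#' @return An object of class `reliability_result` with fields `alpha`,
#'   `mean_r`, `k_raters`, `n_notes`.
#' @export
reliability_summary <- function(matrix) {
  m <- as_rater_matrix(matrix)
  structure(list(alpha = cronbach_alpha(m),
                 mean_r = mean_interitem_correlation(m),
                 k_raters = ncol(m), n_notes = nrow(m)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(render_report(x, format = "text"))
  invisible(x)
}
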