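# Seedable generator of case-note series and rater matrices with known
# statistical structure. Items are independently missing with configurable
# probabilities (Bernoulli missingness), entry counts for averaged-repeat
# sections follow a configurable distribution, and rater disagreement is a
# per-item flip-error model.

#' Define a missingness profile for the synthetic generator
#'
#' Per-item probabilities that each checklist item is missing from a note,
#' a distribution of entry counts for averaged-repeat sections, and a
#' per-section applicability probability. An optional section-absent
#' mixture models correlated missingness (a whole section missing at
#' once); it is off by default because independent item missingness is the
#' simplest model consistent with section-level omission reporting.
#'
#' @param instrument An [audit_instrument()].
#' @param p_missing One of: a scalar probability applied to every item; a
#'   named vector of per-section probabilities; or a named list of named
#'   per-item probability vectors.
#' @param entry_weights Sampling weights over entry counts
#'   `1..max_entries` for averaged-repeat sections; the default is a point
#'   mass on `max_entries` (all four subsequent entries examined, so a
#'   20-note STAR series exposes 160 subsequent-entry points).
#' @param p_applicable Scalar or named per-section probability that the
#'   section is applicable; default 1.
#' @param p_section_absent Scalar or named per-section probability that an
#'   applicable section is missing wholesale (all items absent); default 0.
#' @return An object of class `missingness_profile`.
#' @export
missingness_profile <- function(instrument, p_missing = 0,
                                entry_weights = NULL, p_applicable = 1,
                                p_section_absent = 0) {
  stopifnot(inherits(instrument, "audit_instrument"))
  nms <- names(instrument$sections)
  expand_section <- function(p, nm) {
    ids <- names(instrument$sections[[nm]]$items)
    if (is.list(p)) p <- p[[nm]] %||%
        stop_validation("p_missing: no entry for section '%s'", nm)
    if (!is.null(names(p)) && all(names(p) %in% nms)) p <- p[[nm]]
    if (length(p) == 1L) p <- stats::setNames(rep(as.numeric(p), length(ids)), ids)
    if (!setequal(names(p), ids))
      stop_validation("p_missing for section '%s' must cover item ids %s",
                      nm, toString(ids))
    p[ids]
  }
  items <- lapply(nms, function(nm) {
    p <- expand_section(p_missing, nm)
    if (any(p < 0 | p > 1))
      stop_validation("missing probabilities must lie in [0, 1] (section '%s')", nm)
    p
  })
  names(items) <- nms
  expand_scalar <- function(x, what, lo = 0, hi = 1) {
    if (length(x) == 1L) x <- stats::setNames(rep(as.numeric(x), length(nms)), nms)
    if (!setequal(names(x), nms))
      stop_validation("'%s' must be a scalar or named per-section vector", what)
    x <- x[nms]
    if (any(x < lo | x > hi))
      stop_validation("'%s' must lie in [%g, %g]", what, lo, hi)
    x
  }
  max_e <- max(vapply(instrument$sections, `[[`, integer(1), "max_entries"))
  if (is.null(entry_weights)) {
    entry_weights <- c(rep(0, max_e - 1), 1)
  }
  if (length(entry_weights) > max_e || any(entry_weights < 0) ||
      sum(entry_weights) <= 0)
    stop_validation("'entry_weights' must be non-negative weights over 1..%d", max_e)
  structure(list(
    instrument_name = instrument$name,
    items = items,
    entry_weights = entry_weights / sum(entry_weights),
    p_applicable = expand_scalar(p_applicable, "p_applicable"),
    p_section_absent = expand_scalar(p_section_absent, "p_section_absent")),
    class = "missingness_profile")
}

#' Build a profile from section-level omission rates
#'
#' Inverts an omission table: every item of a section is assigned the
#' uniform missing probability `rate / 100`, so the expected omission
#' table of series generated from the profile reproduces the input rates
#' (expected deductions are linear in the item probabilities).
#'
#' @param instrument An [audit_instrument()].
#' @param section_rates Percent missing per section (named by section or
#'   in instrument order), each in `[0, 100]`.
#' @param ... Passed to [missingness_profile()] (entry weights etc.).
#' @return A `missingness_profile`.
#' @export
profile_from_omission_rates <- function(instrument, section_rates, ...) {
  stopifnot(inherits(instrument, "audit_instrument"))
  nms <- names(instrument$sections)
  if (is.null(names(section_rates))) {
    if (length(section_rates) != length(nms))
      stop_validation("'section_rates' must have one rate per section")
    names(section_rates) <- nms
  }
  if (!setequal(names(section_rates), nms))
    stop_validation("'section_rates' names must match the instrument sections")
  if (any(section_rates < 0 | section_rates > 100))
    stop_validation("omission rates must lie in [0, 100]")
  missingness_profile(instrument,
                      p_missing = as.list(section_rates[nms] / 100), ...)
}

#' Generate a synthetic case-note series
#'
#' Each item of each entry is independently missing with its profile
#' probability; entry counts and section applicability are drawn from the
#' profile. Identical seeds reproduce identical series.
#'
#' @param instrument An [audit_instrument()].
#' @param profile A [missingness_profile()] covering every instrument item.
#' @param n_notes Number of notes to generate.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return List of [case_note()] assessments.
#' @export
generate_series <- function(instrument, profile, n_notes, seed = NULL) {
  stopifnot(inherits(instrument, "audit_instrument"),
            inherits(profile, "missingness_profile"))
  n_notes <- as.integer(n_notes)
  if (is.na(n_notes) || n_notes < 1L)
    stop_validation("'n_notes' must be a positive integer")
  nms <- names(instrument$sections)
  for (nm in nms) {
    ids <- names(instrument$sections[[nm]]$items)
    have <- names(profile$items[[nm]])
    if (is.null(have) || !setequal(have, ids))
      stop_validation("profile does not cover section '%s' (items %s)",
                      nm, toString(setdiff(ids, have)))
  }
  with_seed(seed, {
    lapply(seq_len(n_notes), function(i) {
      sections <- lapply(nms, function(nm) {
        spec <- instrument$sections[[nm]]
        if (runif(1) >= profile$p_applicable[[nm]])
          return(section_assessment(list(), applicable = FALSE))
        k <- if (spec$repeat_policy == "averaged_repeat") {
          sample.int(length(profile$entry_weights), 1,
                     prob = profile$entry_weights)
        } else 1L
        absent <- runif(1) < profile$p_section_absent[[nm]]
        p <- profile$items[[nm]]
        entries <- lapply(seq_len(k), function(j) {
          present <- if (absent) rep(FALSE, length(p))
                     else runif(length(p)) >= p
          stats::setNames(present, names(p))
        })
        section_assessment(entries)
      })
      names(sections) <- nms
      case_note(sprintf("note%04d", i), sections)
    })
  })
}

#' Generate a synthetic rater score matrix
#'
#' Emulates an inter-rater validation design: each rater re-assesses
#' perturbed copies of the same true notes, with every item-presence flag
#' independently flipped with probability `flip_prob` (misreading error),
#' and the perturbed notes are scored. With `flip_prob = 0` all raters
#' agree exactly and alpha is 1; reliability degrades as `flip_prob`
#' grows.
#'
#' @param instrument An [audit_instrument()].
#' @param true_notes List of [case_note()] assessments (the notes all
#'   raters examine).
#' @param n_raters Number of raters (>= 2).
#' @param flip_prob Per-item flip probability in `[0, 0.5]`.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param score One of `"percent"` or `"deductions"`: the per-note value
#'   entered in the matrix (alpha is invariant to this affine choice).
#' @return A [rater_matrix()] of notes x raters.
#' @export
generate_rater_matrix <- function(instrument, true_notes, n_raters,
                                  flip_prob = 0.05, seed = NULL,
                                  score = c("percent", "deductions")) {
  score <- match.arg(score)
  stopifnot(inherits(instrument, "audit_instrument"))
  if (inherits(true_notes, "case_note")) true_notes <- list(true_notes)
  n_raters <- as.integer(n_raters)
  if (is.na(n_raters) || n_raters < 2L)
    stop_validation("'n_raters' must be an integer >= 2")
  if (flip_prob < 0 || flip_prob > 0.5)
    stop_validation("'flip_prob' must lie in [0, 0.5]")
  for (n in true_notes) validate_note(instrument, n)
  with_seed(seed, {
    vals <- vapply(seq_len(n_raters), function(r) {
      vapply(true_notes, function(note) {
        seen <- note
        seen$sections <- lapply(note$sections, function(sa) {
          if (!sa$applicable) return(sa)
          sa$entries <- lapply(sa$entries, function(e)
            xor(e, runif(length(e)) < flip_prob))
          sa
        })
        ns <- score_note(instrument, seen)
        if (score == "percent") ns$percent else ns$total
      }, numeric(1))
    }, numeric(length(true_notes)))
    rater_matrix(vals,
                 note_ids = vapply(true_notes, `[[`, character(1), "note_id"),
                 rater_ids = sprintf("rater%d", seq_len(n_raters)))
  })
}
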