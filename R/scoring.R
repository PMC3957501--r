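# Deduction scoring. One point (the item's deduction) is lost per missing
# item; averaged-repeat sections divide their total deductions by the
# number of entries examined, so per-note deductions can be fractional
# (quarters, thirds, halves). All downstream totals are plain sums.

entry_deduction <- function(section, present) {
  ded <- vapply(section$items, `[[`, integer(1), "deduction")
  sum(ded[!present[names(section$items)]])
}

#' Score one section of a case note
#'
#' Single sections deduct the summed deductions of their missing items.
#' Averaged-repeat sections sum missing-item deductions across all entries
#' examined and divide by the number of entries, keeping the score
#' comparable across notes with different numbers of entries (4 entries
#' with 20 missing items deduct 5 points).
#'
#' @param section An [audit_section()].
#' @param assessment A [section_assessment()] with `applicable = TRUE`.
#' @return Deduction in points, between 0 and the section's `max_points`.
#' @export
score_section <- function(section, assessment) {
  stopifnot(inherits(section, "audit_section"))
  if (inherits(assessment, "case_note"))
    stop_validation("pass a section_assessment, not a case_note")
  if (!inherits(assessment, "section_assessment"))
    assessment <- section_assessment(assessment)
  if (!assessment$applicable)
    stop_validation("section '%s': not-applicable sections are skipped at note level, not scored",
                    section$name)
  k <- length(assessment$entries)
  if (k == 0L)
    stop_validation(paste0(
      "section '%s': no entries to score; mark the section applicable = FALSE ",
      "if it does not exist for this note"), section$name)
  if (section$repeat_policy == "single" && k != 1L)
    stop_validation("section '%s': single sections take exactly one entry (got %d)",
                    section$name, k)
  if (k > section$max_entries)
    stop_validation("section '%s': at most %d entries may be examined (got %d)",
                    section$name, section$max_entries, k)
  ids <- names(section$items)
  per_entry <- vapply(assessment$entries, function(e) {
    if (!is.logical(e) || !setequal(names(e), ids) || anyNA(e))
      stop_validation("section '%s': entry item ids must match the instrument",
                      section$name)
    entry_deduction(section, e)
  }, numeric(1))
  if (section$repeat_policy == "averaged_repeat") sum(per_entry) / k
  else sum(per_entry)
}

#' Score one case note
#'
#' @param instrument An [audit_instrument()].
#' @param note A [case_note()] whose sections match the instrument.
#' @return An object of class `note_score`: per-section deductions (`NA`
#'   for not-applicable sections), total deduction, the applicable-points
#'   denominator, and the note score as a percentage
#'   `100 * (denominator - total) / denominator`.
#' @export
score_note <- function(instrument, note) {
  stopifnot(inherits(instrument, "audit_instrument"))
  validate_note(instrument, note)
  nms <- names(instrument$sections)
  ded <- rep(NA_real_, length(nms))
  names(ded) <- nms
  denom <- 0L
  for (nm in nms) {
    sa <- note$sections[[nm]]
    if (!sa$applicable) next
    ded[[nm]] <- score_section(instrument$sections[[nm]], sa)
    denom <- denom + instrument$sections[[nm]]$max_points
  }
  if (denom == 0L)
    stop_validation("note '%s': no applicable sections, score undefined", note$note_id)
  total <- sum(ded, na.rm = TRUE)
  structure(list(note_id = note$note_id, section_deductions = ded,
                 total = total, denominator = denom,
                 percent = 100 * (denom - total) / denom),
            class = "note_score")
}

#' Score a case-note series
#'
#' Aggregates note scores over a consecutive series. The series score is
#' `100 * (P - D) / P` where `D` is the total deductions and `P` the summed
#' applicable points; for a 20-note series of a 50-point instrument with
#' every section applicable this is the familiar `(1000 - D) / 10`.
#'
#' @param instrument An [audit_instrument()].
#' @param notes List of [case_note()] assessments (N >= 1).
#' @return An object of class `series_score`: per-note scores, the
#'   notes-by-sections deduction matrix, per-section deduction totals,
#'   total deductions, and the series score percentage.
#' @export
score_series <- function(instrument, notes) {
  stopifnot(inherits(instrument, "audit_instrument"))
  if (inherits(notes, "case_note")) notes <- list(notes)
  if (!is.list(notes) || length(notes) == 0L)
    stop_validation("'notes' must be a non-empty list of case notes")
  scored <- lapply(notes, function(n) score_note(instrument, n))
  mat <- do.call(rbind, lapply(scored, `[[`, "section_deductions"))
  rownames(mat) <- vapply(scored, `[[`, character(1), "note_id")
  totals <- colSums(mat, na.rm = TRUE)
  D <- sum(totals)
  denom <- sum(vapply(scored, `[[`, numeric(1), "denominator"))
  structure(list(
    instrument = instrument,
    n_notes = length(notes),
    note_scores = scored,
    per_note = mat,
    section_totals = totals,
    total_deductions = D,
    denominator = denom,
    percent = 100 * (denom - D) / denom,
    from_totals = FALSE,
    any_not_applicable = anyNA(mat)),
    class = "series_score")
}

#' Build a series score from per-section deduction totals
#'
#' Published audit results are typically reported at section granularity:
#' total deductions per section over an N-note series. This constructor
#' rebuilds a `series_score` from that level, assuming every section
#' applicable for every note, so series scores, omission tables and
#' deduction shares can be recomputed from reported tables. Per-note data
#' are absent, so the result cannot feed [compare_series()].
#'
#' @param instrument An [audit_instrument()].
#' @param section_totals Numeric vector of per-section total deductions,
#'   named by section or in instrument order.
#' @param n_notes Number of notes in the series.
#' @return A `series_score`.
#' @export
#' @examples
#' star <- builtin_star()
#' pre <- series_from_totals(star, c(82, 34.56, 3, 22, 9, 16), 20)
#' pre$percent  # 83.344
series_from_totals <- function(instrument, section_totals, n_notes) {
  stopifnot(inherits(instrument, "audit_instrument"))
  n_notes <- as.integer(n_notes)
  if (is.na(n_notes) || n_notes < 1L)
    stop_validation("'n_notes' must be a positive integer")
  nms <- names(instrument$sections)
  if (!is.null(names(section_totals))) {
    if (!setequal(names(section_totals), nms))
      stop_validation("'section_totals' names must match the instrument sections (%s)",
                      toString(nms))
    section_totals <- section_totals[nms]
  } else {
    if (length(section_totals) != length(nms))
      stop_validation("'section_totals' must have one value per section (%d expected)",
                      length(nms))
    names(section_totals) <- nms
  }
  maxima <- vapply(instrument$sections, `[[`, integer(1), "max_points")
  if (any(section_totals < 0) || any(section_totals > maxima * n_notes))
    stop_validation("section totals must lie in [0, max_points * n_notes]")
  D <- sum(section_totals)
  denom <- instrument$points_per_note * n_notes
  structure(list(
    instrument = instrument,
    n_notes = n_notes,
    note_scores = NULL,
    per_note = NULL,
    section_totals = section_totals,
    total_deductions = D,
    denominator = denom,
    percent = 100 * (denom - D) / denom,
    from_totals = TRUE,
    any_not_applicable = FALSE),
    class = "series_score")
}

#' Omission table for a scored series
#'
#' Per-section deductions over the available points (section maximum times
#' the number of notes in which the section was applicable; averaged-repeat
#' sections count their maximum once per note), expressed as percentage of
#' missing information, plus a total row. `pct_complete` is the
#' completeness complement used when reporting section-level improvement.
#'
#' @param series A `series_score`.
#' @return A data frame with columns `section`, `deductions`, `available`,
#'   `pct_missing`, `pct_complete`; the final row is the series total.
#' @export
omission_table <- function(series) {
  stopifnot(inherits(series, "series_score"))
  instr <- series$instrument
  maxima <- vapply(instr$sections, `[[`, integer(1), "max_points")
  n_applicable <- if (is.null(series$per_note)) {
    rep(series$n_notes, length(maxima))
  } else {
    colSums(!is.na(series$per_note))
  }
  avail <- maxima * n_applicable
  ded <- series$section_totals
  out <- data.frame(
    section = c(names(instr$sections), "Total deductions"),
    deductions = c(unname(ded), series$total_deductions),
    available = c(unname(avail), series$denominator),
    stringsAsFactors = FALSE)
  out$pct_missing <- 100 * out$deductions / out$available
  out$pct_complete <- 100 - out$pct_missing
  out
}

#' Per-item contribution to section deductions
#'
#' For every instrument item, the deductions attributable to it across the
#' series, its share of its section's total deductions, and the number of
#' notes in which it was missing at least once. Items of averaged-repeat
#' sections accumulate their per-entry-averaged contributions, so item
#' deductions still sum exactly to the section total. Shares are undefined
#' (`NA`) for sections with zero deductions.
#'
#' @param instrument An [audit_instrument()].
#' @param notes List of [case_note()] assessments.
#' @return A data frame with columns `section`, `item_id`, `label`,
#'   `deductions`, `share_pct`, `n_notes_missing`.
#' @export
item_breakdown <- function(instrument, notes) {
  stopifnot(inherits(instrument, "audit_instrument"))
  if (inherits(notes, "case_note")) notes <- list(notes)
  for (n in notes) validate_note(instrument, n)
  rows <- lapply(names(instrument$sections), function(nm) {
    spec <- instrument$sections[[nm]]
    ids <- names(spec$items)
    ded <- vapply(spec$items, `[[`, integer(1), "deduction")
    item_total <- stats::setNames(numeric(length(ids)), ids)
    n_missing <- stats::setNames(integer(length(ids)), ids)
    for (note in notes) {
      sa <- note$sections[[nm]]
      if (!sa$applicable) next
      k <- length(sa$entries)
      miss_counts <- Reduce(`+`, lapply(sa$entries, function(e) !e[ids]))
      contrib <- ded * miss_counts /
        (if (spec$repeat_policy == "averaged_repeat") k else 1)
      item_total <- item_total + contrib
      n_missing <- n_missing + (miss_counts > 0)
    }
    sec_total <- sum(item_total)
    data.frame(
      section = nm, item_id = ids,
      label = vapply(spec$items, `[[`, character(1), "label"),
      deductions = unname(item_total),
      share_pct = if (sec_total > 0) 100 * unname(item_total) / sec_total
                  else NA_real_,
      n_notes_missing = unname(n_missing),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Share of total deductions contributed by a subset of sections
#'
#' @param series A `series_score` with non-zero total deductions.
#' @param sections Character vector of section names.
#' @return Percentage of the series' total deductions attributable to the
#'   named sections; `NA` (with a warning) when the series has no
#'   deductions at all.
#' @export
#' @examples
#' star <- builtin_star()
#' pre <- series_from_totals(star, c(82, 34.56, 3, 22, 9, 16), 20)
#' deduction_share(pre, c("Initial clerking", "Subsequent entries"))  # ~70
deduction_share <- function(series, sections) {
  stopifnot(inherits(series, "series_score"))
  bad <- setdiff(sections, names(series$section_totals))
  if (length(bad))
    stop_validation("unknown section(s): %s", toString(bad))
  if (series$total_deductions == 0) {
    warning("series has zero total deductions; share is undefined")
    return(NA_real_)
  }
  100 * sum(series$section_totals[sections]) / series$total_deductions
}

#' @export
print.note_score <- function(x, ...) {
  cat(sprintf("<note_score> %s: %.3g of %d points deducted, score %.3f%%\n",
              x$note_id, x$total, x$denominator, x$percent))
  invisible(x)
}

#' @export
print.series_score <- function(x, ...) {
  cat(render_report(x, format = "text"))
  invisible(x)
}
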