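# Structured audit records: one case note = per-section item-presence
# assessments. Presence flags (including legibility) are human judgments
# recorded as data; nothing here inspects note text.

#' Assess one section of a case note
#'
#' @param entries A list of named logical vectors, one per entry examined;
#'   names are the section's item ids and values are TRUE when the item is
#'   present. Single-entry sections take exactly one entry; averaged-repeat
#'   sections take 1 to `max_entries` entries (however many consecutive
#'   entries the auditor examined).
#' @param applicable Set to `FALSE` when the section cannot exist for this
#'   admission (e.g. no operation, hence no consent form); the section then
#'   contributes no deductions and its points leave the note's denominator.
#' @return An object of class `section_assessment`.
#' @export
section_assessment <- function(entries, applicable = TRUE) {
  if (is.logical(entries)) entries <- list(entries)
  if (!is.list(entries))
    stop_validation("'entries' must be a list of named logical vectors")
  structure(list(entries = entries, applicable = isTRUE(applicable)),
            class = "section_assessment")
}

#' Assemble a case-note assessment
#'
#' @param note_id Opaque identifier for the note (no patient identifiers).
#' @param sections Named list of [section_assessment()] objects; names must
#'   match the instrument's section names exactly.
#' @return An object of class `case_note`.
#' @export
case_note <- function(note_id, sections) {
  if (!is.character(note_id) || length(note_id) != 1L || !nzchar(note_id))
    stop_validation("'note_id' must be a non-empty string")
  if (!is.list(sections) || is.null(names(sections)))
    stop_validation("note '%s': 'sections' must be a named list", note_id)
  sections <- lapply(sections, function(s) {
    if (inherits(s, "section_assessment")) s else section_assessment(s)
  })
  structure(list(note_id = note_id, sections = sections), class = "case_note")
}

#' A fully documented case note
#'
#' Convenience constructor for an assessment in which every item of every
#' section is present (zero deductions); useful as a baseline to degrade.
#'
#' @param instrument An [audit_instrument()].
#' @param note_id Note identifier.
#' @param n_entries Number of entries recorded for averaged-repeat
#'   sections; defaults to each section's `max_entries`.
#' @return A [case_note()].
#' @export
perfect_note <- function(instrument, note_id = "note1", n_entries = NULL) {
  sections <- lapply(instrument$sections, function(s) {
    k <- if (s$repeat_policy == "averaged_repeat")
      n_entries %||% s$max_entries else 1L
    entry <- rep(TRUE, length(s$items))
    names(entry) <- names(s$items)
    section_assessment(rep(list(entry), k))
  })
  case_note(note_id, sections)
}

# Validate one case note against an instrument; error messages name the
# note and section so file-level failures are locatable.
validate_note <- function(instrument, note) {
  if (!inherits(note, "case_note"))
    stop_validation("expected a case_note object")
  got <- names(note$sections)
  want <- names(instrument$sections)
  if (!setequal(got, want) || length(got) != length(want)) {
    missing <- setdiff(want, got)
    extra <- setdiff(got, want)
    stop_validation(
      "note '%s': sections do not match instrument '%s'%s%s",
      note$note_id, instrument$name,
      if (length(missing)) paste0("; missing: ", toString(missing)) else "",
      if (length(extra)) paste0("; unknown: ", toString(extra)) else "")
  }
  for (nm in want) {
    spec <- instrument$sections[[nm]]
    sa <- note$sections[[nm]]
    if (!sa$applicable) next
    k <- length(sa$entries)
    if (spec$repeat_policy == "single" && k != 1L)
      stop_validation("note '%s', section '%s': single sections take exactly one entry (got %d)",
                      note$note_id, nm, k)
    if (spec$repeat_policy == "averaged_repeat") {
      if (k < 1L)
        stop_validation(paste0(
          "note '%s', section '%s': an applicable averaged-repeat section needs ",
          "at least one entry; mark it applicable = FALSE if no entries exist"),
          note$note_id, nm)
      if (k > spec$max_entries)
        stop_validation("note '%s', section '%s': at most %d entries may be examined (got %d)",
                        note$note_id, nm, spec$max_entries, k)
    }
    ids <- names(spec$items)
    for (i in seq_along(sa$entries)) {
      e <- sa$entries[[i]]
      if (!is.logical(e) || is.null(names(e)) || anyNA(e))
        stop_validation("note '%s', section '%s', entry %d: entries are named logical vectors without NA",
                        note$note_id, nm, i)
      if (!setequal(names(e), ids) || length(e) != length(ids)) {
        bad <- setdiff(names(e), ids)
        stop_validation(
          "note '%s', section '%s', entry %d: item ids must match the instrument%s",
          note$note_id, nm, i,
          if (length(bad)) paste0("; unknown item id: ", toString(bad)) else "")
      }
    }
  }
  invisible(note)
}
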