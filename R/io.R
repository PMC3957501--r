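# Readers/writers for the JSON and CSV interchange formats, and
# deterministic report rendering. All files are UTF-8; CSV is
# comma-separated with a header row and quoted character fields.

SERIES_FORMAT_VERSION <- 1L

note_to_list <- function(note) {
  list(note_id = note$note_id,
       sections = lapply(note$sections, function(sa) {
         list(applicable = sa$applicable,
              entries = lapply(sa$entries, as.list))
       }))
}

#' Write a case-note series to JSON
#'
#' The document carries a format version, the full inline instrument
#' definition, a provenance block (tool version, timestamp, and the seed
#' when the series is synthetic) and the per-note assessments.
#'
#' @param instrument An [audit_instrument()].
#' @param notes List of [case_note()] assessments.
#' @param path Output file path.
#' @param seed Optional seed recorded in provenance for synthetic series.
#' @return `path`, invisibly.
#' @export
write_series <- function(instrument, notes, path, seed = NULL) {
  stopifnot(inherits(instrument, "audit_instrument"))
  if (inherits(notes, "case_note")) notes <- list(notes)
  for (n in notes) validate_note(instrument, n)
  doc <- list(
    format_version = SERIES_FORMAT_VERSION,
    provenance = c(list(tool = "staraudit",
                        version = as.character(packageVersion("staraudit")),
                        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                   if (!is.null(seed)) list(seed = seed)),
    instrument = instrument_to_list(instrument),
    notes = lapply(notes, note_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a case-note series from JSON
#'
#' Parses and fully validates a series document written by
#' [write_series()] (or produced by hand in the same shape). Validation
#' errors name the offending note and section. The `instrument` field may
#' be an inline definition or the name of a built-in (`"STAR"`,
#' `"CRABEL"`).
#'
#' @param path Path to the JSON document.
#' @return A list with elements `instrument` (an [audit_instrument()]),
#'   `notes` (list of [case_note()]) and `provenance`.
#' @export
read_series <- function(path) {
  if (!file.exists(path))
    stop_validation("series file not found: '%s'", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_validation("malformed JSON in '%s': %s",
                                    path, conditionMessage(e)))
  ver <- doc$format_version %||% stop_validation("'%s': missing format_version", path)
  if (as.integer(ver) != SERIES_FORMAT_VERSION)
    stop_validation("'%s': unsupported format_version %s", path, ver)
  instrument <- load_instrument(doc$instrument %||%
                                  stop_validation("'%s': missing instrument", path))
  if (is.null(doc$notes) || length(doc$notes) == 0L)
    stop_validation("'%s': document contains no notes", path)
  notes <- lapply(doc$notes, function(nd) {
    id <- nd$note_id %||% stop_validation("'%s': note missing note_id", path)
    if (is.null(nd$sections))
      stop_validation("note '%s': missing sections", id)
    sections <- lapply(nd$sections, function(sd) {
      entries <- lapply(sd$entries %||% list(), function(e) {
        v <- vapply(e, function(x) {
          if (!is.logical(x) || length(x) != 1L || is.na(x))
            stop_validation("note '%s': item presence flags must be true/false", id)
          x
        }, logical(1))
        v
      })
      section_assessment(entries, applicable = sd$applicable %||% TRUE)
    })
    case_note(id, sections)
  })
  for (n in notes) validate_note(instrument, n)
  list(instrument = instrument, notes = notes, provenance = doc$provenance)
}

#' Export a series as a flat scoring sheet
#'
#' One row per item per entry per note, mirroring a paper scoring sheet:
#' columns `note_id`, `section`, `entry`, `item_id`, `present`,
#' `deduction`. Sections marked not applicable contribute no rows.
#'
#' @param instrument An [audit_instrument()].
#' @param notes List of [case_note()] assessments.
#' @param path Optional CSV output path; when given, the sheet is written
#'   (UTF-8, comma-separated, header row, quoted strings).
#' @return The sheet as a data frame (invisibly when `path` is given).
#' @export
series_to_sheet <- function(instrument, notes, path = NULL) {
  stopifnot(inherits(instrument, "audit_instrument"))
  if (inherits(notes, "case_note")) notes <- list(notes)
  for (n in notes) validate_note(instrument, n)
  rows <- list()
  for (note in notes) {
    for (nm in names(instrument$sections)) {
      sa <- note$sections[[nm]]
      if (!sa$applicable) next
      spec <- instrument$sections[[nm]]
      ded <- vapply(spec$items, `[[`, integer(1), "deduction")
      for (i in seq_along(sa$entries)) {
        e <- sa$entries[[i]][names(spec$items)]
        rows[[length(rows) + 1L]] <- data.frame(
          note_id = note$note_id, section = nm, entry = i,
          item_id = names(spec$items), present = unname(e),
          deduction = unname(ded), stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, rows)
  rownames(sheet) <- NULL
  if (!is.null(path)) {
    write.csv(sheet, path, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(sheet))
  }
  sheet
}

#' Import a scoring sheet back into a series
#'
#' Inverse of [series_to_sheet()]: notes keep their order of first
#' appearance; instrument sections with no rows for a note are marked not
#' applicable.
#'
#' @param sheet A data frame as produced by [series_to_sheet()], or a path
#'   to such a CSV file.
#' @param instrument An [audit_instrument()].
#' @return List of [case_note()] assessments.
#' @export
sheet_to_series <- function(sheet, instrument) {
  stopifnot(inherits(instrument, "audit_instrument"))
  if (is.character(sheet)) {
    if (!file.exists(sheet))
      stop_validation("scoring sheet not found: '%s'", sheet)
    sheet <- read.csv(sheet, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  need <- c("note_id", "section", "entry", "item_id", "present")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop_validation("scoring sheet missing column(s): %s", toString(miss))
  sheet$present <- as.logical(sheet$present)
  note_ids <- unique(sheet$note_id)
  notes <- lapply(note_ids, function(id) {
    nd <- sheet[sheet$note_id == id, , drop = FALSE]
    sections <- lapply(names(instrument$sections), function(nm) {
      sd <- nd[nd$section == nm, , drop = FALSE]
      if (nrow(sd) == 0L)
        return(section_assessment(list(), applicable = FALSE))
      entries <- lapply(sort(unique(sd$entry)), function(i) {
        ed <- sd[sd$entry == i, , drop = FALSE]
        stats::setNames(ed$present, ed$item_id)
      })
      section_assessment(entries)
    })
    names(sections) <- names(instrument$sections)
    case_note(id, sections)
  })
  for (n in notes) validate_note(instrument, n)
  notes
}

#' Read and write rater score matrices as CSV
#'
#' The CSV layout is one row per note: first column `note_id`, one column
#' per rater.
#'
#' @param path CSV file path.
#' @return `read_rater_matrix()` returns a [rater_matrix()].
#' @export
read_rater_matrix <- function(path) {
  if (!file.exists(path))
    stop_validation("rater matrix file not found: '%s'", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 check.names = FALSE)
  if (ncol(df) < 3L)
    stop_validation("'%s': need a note_id column plus at least two rater columns", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop_validation("'%s': rater columns must be numeric", path)
  rater_matrix(vals, note_ids = as.character(df[[1]]),
               rater_ids = colnames(df)[-1])
}

#' @rdname read_rater_matrix
#' @param matrix A [rater_matrix()].
#' @export
write_rater_matrix <- function(matrix, path) {
  m <- as_rater_matrix(matrix)
  df <- data.frame(note_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a missingness profile definition
#'
#' JSON shape: `{p_missing: number | {section: number | {item: number}},
#' entry_weights?: [w1..], p_applicable?: ..., p_section_absent?: ...}`.
#'
#' @param path JSON file path.
#' @param instrument An [audit_instrument()].
#' @return A [missingness_profile()].
#' @export
read_profile <- function(path, instrument) {
  if (!file.exists(path))
    stop_validation("profile file not found: '%s'", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_validation("malformed JSON in '%s': %s",
                                    path, conditionMessage(e)))
  missingness_profile(
    instrument,
    p_missing = doc$p_missing %||% 0,
    entry_weights = doc$entry_weights,
    p_applicable = doc$p_applicable %||% 1,
    p_section_absent = doc$p_section_absent %||% 0)
}

# -- report rendering -------------------------------------------------------

# Display precision: series/note scores to 3 d.p., omission percentages to
# the nearest integer, deduction shares to 1 d.p. Stored values are never
# rounded; rounding happens only here.

report_list <- function(x) UseMethod("report_list")

#' @export
report_list.series_score <- function(x) {
  om <- omission_table(x)
  list(kind = "series_score",
       instrument = x$instrument$name,
       n_notes = x$n_notes,
       total_deductions = x$total_deductions,
       available_points = x$denominator,
       score_percent = x$percent,
       any_not_applicable = x$any_not_applicable,
       sections = lapply(seq_len(nrow(om)), function(i) as.list(om[i, ])))
}

#' @export
report_list.audit_comparison <- function(x) {
  list(kind = "comparison",
       rows = lapply(seq_len(nrow(x)), function(i)
         as.list(as.data.frame(x)[i, ])),
       note = "No multiple-testing correction applied across section tests.")
}

#' @export
report_list.reliability_result <- function(x) {
  list(kind = "reliability", alpha = x$alpha, mean_interrater_r = x$mean_r,
       k_raters = x$k_raters, n_notes = x$n_notes)
}

#' Render a result as a report
#'
#' Deterministic rendering (identical inputs give byte-identical output;
#' no timestamps) of a scored series, an audit-cycle comparison or a
#' reliability summary, as a plain-text table, a JSON document or CSV.
#'
#' @param x A `series_score`, `audit_comparison` or `reliability_result`.
#' @param format `"text"`, `"json"` or `"csv"`.
#' @return A single string containing the rendered report.
#' @export
render_report <- function(x, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  if (format == "json")
    return(as.character(jsonlite::toJSON(report_list(x), auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  if (format == "csv") return(render_csv(x))
  render_text(x)
}

render_csv <- function(x) UseMethod("render_csv")

#' @export
render_csv.series_score <- function(x) {
  con <- textConnection("out", "w", local = TRUE)
  write.csv(omission_table(x), con, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
render_csv.audit_comparison <- function(x) {
  con <- textConnection("out", "w", local = TRUE)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
render_csv.reliability_result <- function(x) {
  sprintf("statistic,value\ncronbach_alpha,%.3f\nmean_interrater_r,%.3f\nk_raters,%d\nn_notes,%d\n",
          x$alpha, x$mean_r, x$k_raters, x$n_notes)
}

render_text <- function(x) UseMethod("render_text")

#' @export
render_text.series_score <- function(x) {
  om <- omission_table(x)
  body <- sprintf("%-22s %10s / %-6s %4.0f%%",
                  om$section, format(om$deductions, trim = TRUE),
                  format(om$available, trim = TRUE), om$pct_missing)
  paste0(c(
    sprintf("%s series score: %d notes", x$instrument$name, x$n_notes),
    sprintf("%-22s %19s %5s", "Section", "deductions/available", "miss"),
    body,
    sprintf("Series score: %.3f%%", x$percent),
    if (x$any_not_applicable)
      "Note: some sections were marked not applicable; denominators adjusted.",
    ""), collapse = "\n")
}

#' @export
render_text.audit_comparison <- function(x) {
  df <- as.data.frame(x)
  body <- sprintf("%-22s %12.5g %12.5g %8.4g %9.4g  %s",
                  df$field, df$pre_deductions, df$post_deductions,
                  df$U, df$p, df$method)
  paste0(c(
    "Pre- vs post-change audit comparison (Mann-Whitney U, two-sided)",
    sprintf("%-22s %12s %12s %8s %9s  %s",
            "Field", "pre", "post", "U", "p", "method"),
    body,
    "No multiple-testing correction applied across section tests.",
    ""), collapse = "\n")
}

#' @export
render_text.reliability_result <- function(x) {
  paste0(c(
    sprintf("Inter-rater reliability (%d raters x %d notes)",
            x$k_raters, x$n_notes),
    sprintf("Cronbach's alpha:          %.3f", x$alpha),
    sprintf("Mean inter-rater r:        %.3f", x$mean_r),
    ""), collapse = "\n")
}
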