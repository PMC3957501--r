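# Scoring instruments: named sections, each an ordered checklist of items
# with per-item deductions, a per-note point maximum, and a repeat policy
# ("single" or "averaged_repeat" for sections scored over several entries).

#' Define a checklist item
#'
#' One essential entry of a scoring instrument. A fixed number of points is
#' deducted from the section score whenever the item is missing from the
#' note (STAR deducts 1 point for every item).
#'
#' @param id Short stable identifier, unique within the section.
#' @param label Human-readable description of the item.
#' @param deduction Points lost when the item is missing (integer >= 1).
#' @return An object of class `audit_item`.
#' @export
audit_item <- function(id, label = id, deduction = 1L) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_validation("item 'id' must be a non-empty string")
  if (!is.character(label) || length(label) != 1L)
    stop_validation("item '%s': 'label' must be a string", id)
  deduction <- as.integer(deduction)
  if (is.na(deduction) || deduction < 1L)
    stop_validation("item '%s': 'deduction' must be an integer >= 1", id)
  structure(list(id = id, label = label, deduction = deduction),
            class = "audit_item")
}

#' Define an instrument section
#'
#' A section is an ordered checklist of items with a per-note point maximum.
#' `repeat_policy = "single"` sections are assessed once per note;
#' `"averaged_repeat"` sections (STAR's subsequent entries) are assessed on
#' up to `max_entries` consecutive entries and the total deduction is
#' divided by the number of entries examined.
#'
#' @param name Section name, unique within the instrument.
#' @param items Either a list of [audit_item()] objects or a named character
#'   vector mapping item ids to labels (each item then deducts 1 point).
#' @param max_points Per-note point maximum; must equal the sum of item
#'   deductions (per entry, for repeated sections). Defaults to that sum.
#' @param repeat_policy `"single"` or `"averaged_repeat"`.
#' @param max_entries Maximum number of entries examined for
#'   `"averaged_repeat"` sections (STAR uses 4).
#' @return An object of class `audit_section`.
#' @export
audit_section <- function(name, items, max_points = NULL,
                          repeat_policy = c("single", "averaged_repeat"),
                          max_entries = NULL) {
  repeat_policy <- match.arg(repeat_policy)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("section 'name' must be a non-empty string")
  if (is.character(items)) {
    ids <- names(items)
    if (is.null(ids) || any(!nzchar(ids)))
      stop_validation("section '%s': character 'items' must be named id = label", name)
    items <- Map(audit_item, ids, unname(items))
  }
  if (!is.list(items) || length(items) == 0L)
    stop_validation("section '%s': 'items' must be a non-empty list", name)
  items <- lapply(items, function(it) {
    if (inherits(it, "audit_item")) it
    else if (is.list(it)) do.call(audit_item, it[c("id", "label", "deduction")])
    else stop_validation("section '%s': invalid item definition", name)
  })
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop_validation("section '%s': duplicate item id '%s'",
                    name, ids[duplicated(ids)][1])
  names(items) <- ids
  per_entry <- sum(vapply(items, `[[`, integer(1), "deduction"))
  if (is.null(max_points)) max_points <- per_entry
  max_points <- as.integer(max_points)
  if (is.na(max_points) || max_points < 1L)
    stop_validation("section '%s': 'max_points' must be a positive integer", name)
  if (per_entry != max_points)
    stop_validation(
      "section '%s': item deductions sum to %d but 'max_points' is %d",
      name, per_entry, max_points)
  if (repeat_policy == "single") {
    if (!is.null(max_entries) && as.integer(max_entries) != 1L)
      stop_validation("section '%s': 'single' sections must have max_entries 1", name)
    max_entries <- 1L
  } else {
    if (is.null(max_entries)) max_entries <- 4L
    max_entries <- as.integer(max_entries)
    if (is.na(max_entries) || max_entries < 1L)
      stop_validation("section '%s': 'max_entries' must be a positive integer", name)
  }
  structure(list(name = name, items = items, max_points = max_points,
                 repeat_policy = repeat_policy, max_entries = max_entries),
            class = "audit_section")
}

#' Define a scoring instrument
#'
#' @param name Instrument name.
#' @param sections Ordered list of [audit_section()] objects.
#' @return An object of class `audit_instrument` with `points_per_note`
#'   equal to the sum of section maxima.
#' @export
audit_instrument <- function(name, sections) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("instrument 'name' must be a non-empty string")
  if (!is.list(sections) || length(sections) == 0L)
    stop_validation("instrument '%s': 'sections' must be a non-empty list", name)
  if (!all(vapply(sections, inherits, logical(1), "audit_section")))
    stop_validation("instrument '%s': every section must be an audit_section", name)
  nms <- vapply(sections, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop_validation("instrument '%s': duplicate section name '%s'",
                    name, nms[duplicated(nms)][1])
  names(sections) <- nms
  structure(list(name = name, sections = sections,
                 points_per_note = sum(vapply(sections, `[[`, integer(1),
                                              "max_points"))),
            class = "audit_instrument")
}

#' Section names and weights of an instrument
#'
#' The weight of a section is its per-note point maximum as a percentage of
#' the instrument's points per note (STAR: 20/16/14/14/18/18; CRABEL:
#' 20/60/10/10).
#'
#' @param instrument An [audit_instrument()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
section_weights <- function(instrument) {
  stopifnot(inherits(instrument, "audit_instrument"))
  maxima <- vapply(instrument$sections, `[[`, integer(1), "max_points")
  100 * maxima / instrument$points_per_note
}

#' The STAR instrument
#'
#' The built-in Surgical Tool for Auditing Records: 50 essential items over
#' six sections (initial clerking 10, subsequent entries 8, consent 7,
#' anaesthetic record 7, operative record 9, discharge summary 9), one
#' point deducted per missing item. The subsequent-entries section is
#' scored over up to four consecutive entries and its deductions are
#' averaged over the number of entries examined. Entry legibility (two
#' illegible words render an entry illegible) is an assessor judgment
#' recorded as an item flag, never computed.
#'
#' @return An `audit_instrument` with `points_per_note = 50`.
#' @export
builtin_star <- function() {
  audit_instrument("STAR", list(
    audit_section("Initial clerking", c(
      patient_name      = "Patient name at the top of the clerking section",
      hospital_number   = "Patient hospital number",
      referral_source   = "Referral source (GP, A&E, ...)",
      consultant        = "Consultant in charge",
      date_time         = "Date and time the patient was seen",
      working_diagnosis = "Working diagnosis",
      investigations    = "Investigations ordered and results available",
      management_plan   = "Initial management plan",
      allergies         = "Allergies",
      clinician_details = "Name, post and bleep number of the person creating the entry")),
    audit_section("Subsequent entries", c(
      patient_details   = "Patient name and hospital number on the continuation sheet",
      date_time         = "Date and time of the entry",
      heading           = "An entry heading",
      patient_status    = "Comment on observations or the general state of the patient",
      results           = "Pertinent results",
      management_plan   = "A management plan",
      clinician_details = "Signature, name, bleep number and post",
      legible           = "Entry legible (two illegible words render the entry illegible)"),
      repeat_policy = "averaged_repeat", max_entries = 4L),
    audit_section("Consent", c(
      patient_details = "Patient name, hospital number and the date",
      operation       = "Operation performed",
      site_side       = "Site and side in full words",
      benefits        = "Benefits of the intended procedure",
      risks           = "Risks and complications",
      signatures      = "Signatures of the patient and the consenting doctor",
      doctor_details  = "Name, post and bleep number of the consenting doctor")),
    audit_section("Anaesthetic record", c(
      anaesthetist_name    = "Name of anaesthetist",
      preop_assessment     = "Preoperative assessment",
      drugs_doses          = "Drugs and doses given during anaesthesia",
      monitoring           = "Presence of monitoring data",
      iv_fluids            = "Intravenous fluids given during anaesthesia",
      postop_instructions  = "Postanaesthetic instructions",
      signature            = "Name and signature of the person making the entry")),
    audit_section("Operative record", c(
      patient_details     = "Patient name, hospital number and date of operation",
      surgeon             = "Name of the operating surgeon",
      postop_diagnosis    = "Diagnosis after the procedure",
      findings            = "Description of operative findings",
      tissues_removed     = "Details of tissues removed",
      sutures             = "Details of sutures used",
      prosthetics         = "Prosthetics with serial numbers if used",
      postop_instructions = "Postoperative instructions",
      signature           = "Surgeon's name and signature")),
    audit_section("Discharge summary", c(
      patient_details = "Patient name, hospital number and address",
      dates           = "Admission and discharge dates",
      consultant      = "Discharging consultant",
      diagnosis       = "Diagnosis at discharge",
      investigations  = "Pertinent investigations and results",
      procedures      = "Operations and procedures undertaken",
      complications   = "Presence or absence of complications",
      medications     = "Medications on discharge",
      follow_up       = "Follow-up arrangements"))))
}

#' The CRABEL comparator instrument
#'
#' The four-section CRABEL (Crawford-Beresford-Lafferty) note-keeping score
#' used as a comparator: initial clerking 10 points, subsequent entries 30,
#' consent 5, discharge summary 5 (weights 20/60/10/10 of 50 points per
#' note). The section maxima are fixed and sufficient for section-level
#' deduction scoring; the per-item checklists are provisional placeholders
#' (the original item-level CRABEL checklist is published separately) and
#' can be replaced via [load_instrument()].
#'
#' @return An `audit_instrument` with `points_per_note = 50` and section
#'   maxima 10, 30, 5, 5.
#' @export
builtin_crabel <- function() {
  placeholder <- function(prefix, n) {
    ids <- sprintf("%s_%02d", prefix, seq_len(n))
    labels <- sprintf("Provisional CRABEL item %d (replace via instrument config)",
                      seq_len(n))
    names(labels) <- ids
    labels
  }
  audit_instrument("CRABEL", list(
    audit_section("Initial clerking", placeholder("clerking", 10)),
    audit_section("Subsequent entries", placeholder("subsequent", 30)),
    audit_section("Consent", placeholder("consent", 5)),
    audit_section("Discharge summary", placeholder("discharge", 5))))
}

# -- serialization ----------------------------------------------------------

instrument_to_list <- function(instrument) {
  list(
    name = instrument$name,
    sections = lapply(unname(instrument$sections), function(s) {
      out <- list(name = s$name, max_points = s$max_points,
                  repeat_policy = s$repeat_policy,
                  items = lapply(unname(s$items), function(it)
                    list(id = it$id, label = it$label, deduction = it$deduction)))
      if (s$repeat_policy == "averaged_repeat") out$max_entries <- s$max_entries
      out
    }))
}

#' Write an instrument definition to JSON
#'
#' @param instrument An [audit_instrument()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "audit_instrument"))
  jsonlite::write_json(instrument_to_list(instrument), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load an instrument definition
#'
#' Reads and validates a declarative instrument configuration: a JSON
#' document `{name, sections: [{name, max_points, repeat_policy,
#' max_entries?, items: [{id, label, deduction}]}]}`. All instrument
#' invariants are checked; a max_points value inconsistent with the item
#' deductions is a consistency error. The built-in definitions are shipped
#' as `star.json` and `crabel.json` under the package's `extdata`.
#'
#' @param x Path to a JSON file, or an already-parsed list in the same
#'   shape, or one of the built-in names `"STAR"` / `"CRABEL"`.
#' @return A validated [audit_instrument()].
#' @export
#' @examples
#' star <- load_instrument(system.file("extdata", "star.json",
#'                                     package = "staraudit"))
#' identical(star$points_per_note, builtin_star()$points_per_note)
load_instrument <- function(x) {
  if (inherits(x, "audit_instrument")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (toupper(x) == "STAR") return(builtin_star())
    if (toupper(x) == "CRABEL") return(builtin_crabel())
    if (!file.exists(x))
      stop_validation("instrument file not found: '%s'", x)
    x <- tryCatch(jsonlite::read_json(x, simplifyVector = FALSE),
                  error = function(e)
                    stop_validation("malformed instrument JSON: %s",
                                    conditionMessage(e)))
  }
  if (!is.list(x)) stop_validation("instrument definition must be a JSON object")
  if (is.null(x$name)) stop_validation("instrument definition: missing field 'name'")
  if (is.null(x$sections) || length(x$sections) == 0L)
    stop_validation("instrument '%s': missing or empty field 'sections'", x$name)
  sections <- lapply(x$sections, function(s) {
    for (f in c("name", "max_points", "items"))
      if (is.null(s[[f]]))
        stop_validation("instrument '%s': section missing field '%s'", x$name, f)
    items <- lapply(s$items, function(it) {
      if (is.null(it$id))
        stop_validation("instrument '%s', section '%s': item missing field 'id'",
                        x$name, s$name)
      audit_item(it$id, it$label %||% it$id, it$deduction %||% 1L)
    })
    audit_section(s$name, items, max_points = s$max_points,
                  repeat_policy = s$repeat_policy %||% "single",
                  max_entries = s$max_entries)
  })
  audit_instrument(x$name, sections)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.audit_instrument <- function(x, ...) {
  cat(sprintf("<audit_instrument> %s: %d sections, %d points per note\n",
              x$name, length(x$sections), x$points_per_note))
  w <- section_weights(x)
  for (s in x$sections)
    cat(sprintf("  %-20s %2d points (%d items, %s)  weight %g%%\n",
                s$name, s$max_points, length(s$items),
                if (s$repeat_policy == "averaged_repeat")
                  sprintf("averaged over <= %d entries", s$max_entries)
                else "single entry",
                w[[s$name]]))
  invisible(x)
}
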