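star <- builtin_star()
sub_spec <- star$sections[["Subsequent entries"]]

# four entries, `miss` items missing in each
sub_assessment <- function(miss_per_entry) {
  ids <- names(sub_spec$items)
  section_assessment(lapply(miss_per_entry, function(m) {
    e <- stats::setNames(rep(TRUE, length(ids)), ids)
    if (m > 0) e[seq_len(m)] <- FALSE
    e
  }))
}

test_that("subsequent-entries deductions are averaged over entries examined", {
  # 4 entries, 20 missing items in total -> 5 points
  expect_equal(score_section(sub_spec, sub_assessment(c(5, 5, 5, 5))), 5)
  expect_equal(score_section(sub_spec, sub_assessment(c(8, 8, 4, 0))), 5)
  # 3 entries with 2, 3, 4 missing -> 9/3 = 3 points
  expect_equal(score_section(sub_spec, sub_assessment(c(2, 3, 4))), 3)
  # a single entry is not averaged down
  expect_equal(score_section(sub_spec, sub_assessment(6)), 6)
  # everything present -> 0
  expect_equal(score_section(sub_spec, sub_assessment(c(0, 0, 0, 0))), 0)
})

test_that("applicable sections with zero entries are an explicit error", {
  expect_error(score_section(sub_spec, section_assessment(list())),
               "applicable = FALSE", class = "staraudit_validation_error")
  expect_error(score_section(sub_spec, sub_assessment(c(1, 1, 1, 1, 1))),
               "at most 4", class = "staraudit_validation_error")
})

test_that("note scores sum section deductions against the 50-point maximum", {
  perfect <- perfect_note(star)
  ps <- score_note(star, perfect)
  expect_equal(ps$total, 0)
  expect_equal(ps$percent, 100)

  # every item missing in every entry -> all 50 points lost
  worst <- audit_note(star, "worst",
                      missing = lapply(star$sections, function(s) names(s$items)))
  ws <- score_note(star, worst)
  expect_equal(ws$total, 50)
  expect_equal(ws$percent, 0)

  # consent 1 missing + operative 2 missing -> 47/50 = 94%
  note <- audit_note(star, "n3", missing = list(
    "Consent" = "risks",
    "Operative record" = c("sutures", "findings")))
  ns <- score_note(star, note)
  expect_equal(ns$total, 3)
  expect_equal(ns$percent, 94)
  expect_equal(unname(ns$section_deductions[["Consent"]]), 1)
  expect_equal(unname(ns$section_deductions[["Operative record"]]), 2)
})

test_that("notes that do not match the instrument are rejected by name", {
  note <- audit_note(star, "odd")
  note$sections[["Consent"]] <- NULL
  expect_error(score_note(star, note), "note 'odd'.*missing: Consent",
               class = "staraudit_validation_error")

  note2 <- audit_note(star, "bad_item")
  names(note2$sections[["Consent"]]$entries[[1]])[1] <- "not_an_item"
  expect_error(score_note(star, note2), "Consent",
               class = "staraudit_validation_error")
})

test_that("series scores follow 100 * (P - D) / P and the 20-note shortcut", {
  pre <- series_from_totals(star, c(
    "Initial clerking" = 82, "Subsequent entries" = 34.56, "Consent" = 3,
    "Anaesthetic record" = 22, "Operative record" = 9,
    "Discharge summary" = 16), 20)
  expect_equal(pre$total_deductions, 166.56)
  expect_equal(pre$percent, 83.344)
  expect_equal(pre$percent, (1000 - pre$total_deductions) / 10)

  post <- series_from_totals(star, c(7, 6.25, 1, 8, 0, 1), 20)
  expect_equal(post$total_deductions, 23.25)
  expect_equal(post$percent, 97.675)

  one <- score_series(star, list(perfect_note(star)))
  expect_equal(one$total_deductions, 0)
  expect_equal(one$percent, 100)

  expect_error(score_series(star, list()), "non-empty",
               class = "staraudit_validation_error")
  expect_error(series_from_totals(star, c(500, 0, 0, 0, 0, 0), 20),
               class = "staraudit_validation_error")
})

test_that("not-applicable sections adjust the denominator and nothing else", {
  # day-case note without operation: consent/anaesthetic/operative absent
  note <- audit_note(star, "daycase",
                     missing = list("Initial clerking" = "allergies"),
                     na_sections = c("Consent", "Anaesthetic record",
                                     "Operative record"))
  ns <- score_note(star, note)
  expect_equal(ns$denominator, 10 + 8 + 9)
  expect_equal(ns$total, 1)
  expect_equal(ns$percent, 100 * 26 / 27)

  ss <- score_series(star, list(note, perfect_note(star, "full")))
  expect_true(ss$any_not_applicable)
  expect_equal(ss$denominator, 27 + 50)
  # omission table counts only notes where the section applied
  om <- omission_table(ss)
  expect_equal(om$available[om$section == "Consent"], 7)
  expect_equal(om$available[om$section == "Initial clerking"], 20)

  # with everything applicable the standard fixed denominator is recovered
  all_app <- score_series(star, list(perfect_note(star, "a"),
                                     perfect_note(star, "b")))
  expect_equal(all_app$denominator, 100)
  expect_false(all_app$any_not_applicable)
})

test_that("omission table reproduces deductions over available points", {
  pre <- series_from_totals(star, c(82, 34.56, 3, 22, 9, 16), 20)
  om <- omission_table(pre)
  expect_equal(om$section[1], "Initial clerking")
  expect_equal(om$pct_missing[om$section == "Initial clerking"], 41)
  expect_equal(om$available[om$section == "Initial clerking"], 200)
  # averaged-repeat section exposes its maximum once per note
  expect_equal(om$available[om$section == "Subsequent entries"], 160)
  expect_equal(om$pct_missing[om$section == "Subsequent entries"], 21.6)
  total <- om[om$section == "Total deductions", ]
  expect_equal(total$deductions, 166.56)
  expect_equal(total$pct_missing, 16.656)
  # zero-deduction sections read 0% missing
  empty <- omission_table(score_series(star, list(perfect_note(star))))
  expect_true(all(empty$pct_missing == 0))
  expect_true(all(empty$pct_complete == 100))
})

test_that("deduction shares partition the series total", {
  pre <- series_from_totals(star, c(82, 34.56, 3, 22, 9, 16), 20)
  expect_equal(round(deduction_share(
    pre, c("Initial clerking", "Subsequent entries")), 1), 70.0)
  expect_equal(round(deduction_share(pre, "Initial clerking"), 1), 49.2)
  # 34.56/166.56 = 20.749...; reported alongside 49.2 it complements the
  # combined 70.0% share
  expect_equal(deduction_share(pre, "Subsequent entries"),
               100 * 34.56 / 166.56)
  expect_equal(deduction_share(pre, c("Initial clerking",
                                      "Subsequent entries")),
               deduction_share(pre, "Initial clerking") +
                 deduction_share(pre, "Subsequent entries"))
  expect_equal(deduction_share(pre, names(star$sections)), 100)
  expect_error(deduction_share(pre, "No such section"), "unknown",
               class = "staraudit_validation_error")
  zero <- score_series(star, list(perfect_note(star)))
  expect_warning(s <- deduction_share(zero, "Consent"), "undefined")
  expect_true(is.na(s))
})

test_that("item breakdown attributes deductions to items and sums to 100%", {
  notes <- list(
    audit_note(star, "n1", missing = list("Consent" = c("risks", "benefits"))),
    audit_note(star, "n2", missing = list("Consent" = "risks")))
  bd <- item_breakdown(star, notes)
  cons <- bd[bd$section == "Consent", ]
  expect_equal(cons$deductions[cons$item_id == "risks"], 2)
  expect_equal(cons$share_pct[cons$item_id == "risks"], 100 * 2 / 3)
  expect_equal(sum(cons$share_pct), 100)
  expect_equal(cons$n_notes_missing[cons$item_id == "risks"], 2)
  # zero-deduction sections have undefined (absent) shares, not zeros
  expect_true(all(is.na(bd$share_pct[bd$section == "Discharge summary"])))
  # a section fed by a single item gives that item 100%
  one <- item_breakdown(star, list(
    audit_note(star, "o", missing = list("Operative record" = "sutures"))))
  op <- one[one$section == "Operative record", ]
  expect_equal(op$share_pct[op$item_id == "sutures"], 100)

  # averaged-repeat items accumulate per-entry-averaged contributions that
  # still sum to the section total
  mixed <- audit_note(star, "m", missing = list(
    "Subsequent entries" = list("date_time", c("date_time", "legible"),
                                character(), "heading")))
  bd2 <- item_breakdown(star, list(mixed))
  subs <- bd2[bd2$section == "Subsequent entries", ]
  expect_equal(sum(subs$deductions),
               score_section(sub_spec,
                             mixed$sections[["Subsequent entries"]]))
  expect_equal(subs$deductions[subs$item_id == "date_time"], 2 / 4)
})

test_that("scoring matches an independent item-counting oracle on random series", {
  for (seed in c(11, 23, 47, 101)) {
    rs <- random_series(star, seed)
    got <- score_series(star, rs$notes)
    want <- oracle_series(star, rs$notes)
    expect_equal(got$section_totals, want$section_totals, tolerance = 1e-12)
    expect_equal(got$total_deductions, want$D, tolerance = 1e-12)
    expect_equal(got$percent, want$percent, tolerance = 1e-12)
    expect_equal(vapply(got$note_scores, `[[`, numeric(1), "total"),
                 want$per_note_total, tolerance = 1e-12)
  }
  # and under the CRABEL comparator too
  crabel <- builtin_crabel()
  rs <- random_series(crabel, 7)
  expect_equal(score_series(crabel, rs$notes)$total_deductions,
               oracle_series(crabel, rs$notes)$D, tolerance = 1e-12)
})

test_that("deductions are conserved and scores bounded on random series", {
  for (seed in 1:8) {
    rs <- random_series(star, seed + 300)
    ss <- score_series(star, rs$notes)
    totals <- vapply(ss$note_scores, `[[`, numeric(1), "total")
    expect_equal(sum(ss$section_totals), ss$total_deductions, tolerance = 1e-12)
    expect_equal(sum(totals), ss$total_deductions, tolerance = 1e-12)
    pcts <- vapply(ss$note_scores, `[[`, numeric(1), "percent")
    expect_true(all(pcts >= 0 & pcts <= 100))
    expect_true(ss$percent >= 0 && ss$percent <= 100)
    maxima <- vapply(star$sections, `[[`, integer(1), "max_points")
    ok <- sweep(ss$per_note, 2, maxima, function(d, m)
      is.na(d) | (d >= 0 & d <= m))
    expect_true(all(ok))
  }
})

test_that("marking one more item missing never improves the series score", {
  set.seed(99)
  for (rep in 1:10) {
    rs <- random_series(star, 400 + rep, n_notes = 4)
    notes <- rs$notes
    before <- score_series(star, notes)
    # flip one randomly chosen present item to missing
    j <- sample(length(notes), 1)
    nm <- sample(names(star$sections), 1)
    sa <- notes[[j]]$sections[[nm]]
    if (!sa$applicable) next
    k <- sample(length(sa$entries), 1)
    present_ids <- names(which(sa$entries[[k]]))
    if (length(present_ids) == 0) next
    id <- sample(present_ids, 1)
    notes[[j]]$sections[[nm]]$entries[[k]][[id]] <- FALSE
    after <- score_series(star, notes)
    expect_gte(after$total_deductions, before$total_deductions)
    expect_lte(after$percent, before$percent)
  }
})

test_that("STAR and CRABEL agree at section level on shared deduction inputs", {
  # same section-level deduction totals scored under either instrument
  # reproduce each instrument's own formula output
  crabel <- builtin_crabel()
  star4 <- c("Initial clerking" = 41, "Subsequent entries" = 21.5,
             "Consent" = 8, "Anaesthetic record" = 8,
             "Operative record" = 4, "Discharge summary" = 17)
  crabel4 <- c("Initial clerking" = 33, "Subsequent entries" = 54,
               "Consent" = 5, "Discharge summary" = 6)
  s <- series_from_totals(star, star4, 20)
  c2 <- series_from_totals(crabel, crabel4, 20)
  expect_equal(s$percent, (1000 - sum(star4)) / 10)
  expect_equal(c2$percent, (1000 - sum(crabel4)) / 10)
  expect_equal(c2$percent, 90.2)
})
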