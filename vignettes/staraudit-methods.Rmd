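---
title: "Auditing case-note completeness with staraudit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing case-note completeness with staraudit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staraudit)
```

## The measurement model

`staraudit` scores the completeness of clinical case notes against a
checklist instrument. An instrument is a fixed set of sections, each an
ordered list of essential items with a per-note point maximum; an audit
assessment records, for every item of every note, whether the item was
present. Scoring is by deduction: each missing item removes its deduction
(one point for every STAR item) from the note's maximum.

The built-in STAR instrument has six sections and 50 points per note:
initial clerking (10), subsequent entries (8), consent (7), anaesthetic
record (7), operative record (9) and discharge summary (9), giving section
weights of 20/16/14/14/18/18 percent. The CRABEL comparator has four
sections weighted 20/60/10/10 (maxima 10/30/5/5). Because CRABEL's
item-level checklist is published elsewhere, the built-in carries the four
fixed section maxima — sufficient for all section-level arithmetic — with
provisional placeholder items that a deployment should replace through the
JSON instrument configuration (`load_instrument()`); the configuration is
declarative data, so a hospital can adapt checklists without touching the
engine.

### The subsequent-entries averaging rule

Progress entries accumulate, so a section that examined four entries would
otherwise be penalised four times as heavily as one that examined one.
STAR's rule: examine up to four consecutive entries, sum the missing-item
deductions across them, and divide by the number of entries examined. Four
entries with twenty missing items deduct five points. Which consecutive
entries are examined is the auditor's choice and is recorded in the
assessment; the engine imposes no selection rule. An applicable
averaged-repeat section with zero recorded entries is an error (the rule's
denominator would vanish); the caller must mark the section not
applicable instead.

Entry legibility is one of the eight subsequent-entry items. It is an
assessor judgment (two illegible words render an entry illegible) recorded
as a boolean — the package never inspects note text.

### Note, series and omission scores

For one note, the score is `100 * (P - D) / P`, with `D` the summed
section deductions and `P` the applicable points (50 when every STAR
section applies). For a series the same formula is applied to the summed
deductions and summed applicable points; a 20-note all-applicable STAR
series reduces to the familiar `(1000 - D) / 10`.

Sections that cannot exist for an admission (no operation performed, hence
no consent form, anaesthetic or operative record) may be flagged
`applicable = FALSE`. They contribute no deductions and their maximum
leaves the denominator, so a day-case note is not penalised for forms that
could never have been written. When every section applies, the standard
fixed-denominator formula is recovered exactly; reports flag any
not-applicable usage. This is a deliberate extension: the classical
description is silent on inapplicable sections, and silently scoring them
as missing would bias a unit that handles many day cases.

The omission table reports, per section, deductions over available points
(the section maximum times the number of notes in which it applied;
averaged-repeat sections count their maximum once per note) as percent
missing, with the completeness complement used when quoting section-level
improvement. `item_breakdown()` attributes deductions to individual items
— averaged-repeat items accumulate their per-entry-averaged contributions,
so item deductions still sum exactly to their section total — and reports
each item's share of its section's deductions. Shares of a section with
zero deductions are undefined and reported as `NA`, never as zero.
`series_from_totals()` rebuilds a series score from per-section deduction
totals, because published audit results are typically reported at exactly
that granularity; such a series carries no per-note data and therefore
cannot feed the audit-cycle comparison.

### Numerical representation

Deductions are held as doubles. The only non-integer step in the engine is
the single averaged-repeat division per section per note, so accumulated
error is below 1e-12 — far below the hundredth-of-a-point precision at
which scores are quoted. Stored values are never rounded; rounding is a
display concern only (series scores to 3 decimal places, omission
percentages to the nearest integer, deduction shares to 1 decimal place).
One consequence worth stating: a reported aggregate like a 34.56-point
averaged-section total cannot arise exactly from the averaging rule with
whole-point items over at most four entries (its fractional part is not a
multiple of a twelfth); section-level totals taken from published tables
are therefore treated as inputs in their own right via
`series_from_totals()`, not reverse-engineered into fictitious per-note
assessments.

## Inter-rater reliability

Instrument validation uses a complete notes-by-raters score matrix (for
example seven doctors independently scoring the same four notes).
`cronbach_alpha()` treats raters as the items of a consistency analysis:

$$\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)$$

with `k` raters, `s_i^2` the sample variance (n − 1 denominator) of rater
i's scores across notes and `s_T^2` the sample variance of the per-note
sums. Sample variances are used throughout; with only four notes the n
versus n − 1 choice materially changes alpha, so the choice is stated
here prominently. Alpha is invariant under jointly shifting or positively
rescaling all raters' scores, so percentage scores and raw deductions give
identical values. `mean_interitem_correlation()` is the arithmetic mean of
the `k(k-1)/2` pairwise Pearson correlations, and
`standardised_alpha(r, k) = k r / (1 + (k-1) r)` coincides with alpha
whenever rater variances are equal — a closed-form cross-check used in the
test suite. Degenerate designs fail loudly: fewer than two raters or
notes, incomplete cells, zero total-score variance (alpha undefined) and
zero-variance raters (correlations undefined, the offending rater is
named). No imputation is attempted; the validation design is complete by
construction. Kappa statistics and ICC variants are out of scope.

## Audit-cycle comparison

Pre- and post-intervention series are compared per section (and overall)
with the Mann-Whitney U test on per-note deductions. Audit deductions are
heavily tied small numbers, which drives the design:

* U is computed from rank sums with midranks for ties.
* For `n1 + n2 <= 20` the p-value is exact by full enumeration of all
  `choose(n1 + n2, n1)` assignments of the observed ranks to groups —
  valid with and without ties. The two-sided exact p is the permutation
  probability of a U at least as far from `n1 n2 / 2` as observed (the
  enumeration distribution is symmetric about that centre, because
  reflecting the rank multiset maps it onto itself).
* Larger samples use the normal approximation with tie-corrected variance
  and a 0.5 continuity correction.

Both paths are labelled in the output (`method` column). Two-sided tests
are the default, since an audit comparison asks for a difference, not a
direction. Whether one tests per-note section deductions or per-note
section percentages is immaterial for equal denominators — the transform
is strictly monotone, so U and p coincide; the engine tests deductions and
the invariance is asserted in the suite. No multiple-testing correction is
applied across the section tests, and the report footer says so.

## The synthetic generator

`generate_series()` emulates an audited note series: every item of every
entry is independently missing with its profile probability (Bernoulli
missingness), entry counts for averaged-repeat sections follow a
configurable distribution, and sections may be randomly inapplicable. The
defaults encode the canonical study conditions: series of 20 notes, all
four subsequent entries examined (so a 20-note STAR series exposes
160 subsequent-entry points), every section applicable.
`profile_from_omission_rates()` inverts an omission table into a uniform
per-item profile, so expected generated omission rates equal the input
rates (expected deductions are linear in item probabilities).
`generate_rater_matrix()` emulates an inter-rater validation: each rater
scores perturbed copies of the same true notes with every presence flag
independently flipped with probability epsilon; reliability is perfect at
epsilon 0 and degrades as epsilon grows.

Independence of missingness across items and notes is the simplest model
consistent with section-level omission reporting, and it is what the
recovery and expectation properties in the test suite are proved against.
Real notes are not like this in at least three ways: omissions cluster
(a missing proforma empties a whole section — the optional
`p_section_absent` mixture models exactly this and is off by default),
item presence correlates with clinician and time of day, and rater
disagreement is not symmetric-random but concentrated on ambiguous items.
Passing the generator-backed tests therefore demonstrates that the engine
and statistics are correct under the stated model, not that the model
captures every feature of hospital data.

## Problem sizes and test design

The suite validates the scoring engine against an independent
item-counting oracle on 1,000 seeded random series of up to 10 notes,
checks exact Mann-Whitney p-values against full bitmask enumeration for
combined samples up to 16 (with and without ties) and against the
standard implementation on the untied path, checks alpha against the
covariance-matrix identity and the standardised closed form, and checks
generator parameter recovery on a 10,000-note series against exact
binomial 99% central intervals per item. Fifty simultaneous 99% interval
checks are expected to produce occasional boundary cases by construction,
so the calibrated joint criterion — at most 3 of ~50 items outside — is
asserted rather than the miscalibrated all-inside version. Monte-Carlo
means are asserted within three standard errors of their closed-form
expectations.

## Known limitations

* Assessments are structured booleans produced by a human auditor; there
  is no natural-language processing, OCR or handwriting analysis.
* The CRABEL built-in is exact only at section level until a deployment
  supplies the item-level checklist.
* The exact Mann-Whitney path enumerates `choose(n1 + n2, n1)`
  assignments; beyond a combined sample of about 20 the tie-corrected
  normal approximation is used (the two agree to well under 0.01 in p at
  the crossover sizes).
* Note identifiers are treated as opaque; the package deliberately
  handles no patient-identifiable data.
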