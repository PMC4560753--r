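---
title: "The Adhesion Risk Score: model, validation rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Adhesion Risk Score: model, validation rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesionrisk)
```

## The model

The Adhesion Risk Score is a weighted additive prognostic index in the
tradition of expert-consensus clinical scores (Charlson, POSSUM):
each risk factor carries a fixed integer weight between 0 and 4, the
sub-score is the plain sum, and the sum is read against fixed interval
thresholds. There is no fitted model, no interaction and no calibration
to outcome probabilities — the score was constructed by an expert
consensus process because the published evidence on the relative
importance of individual adhesion risk factors is too heterogeneous to
support a regression-based score. The package therefore treats the
weight tables and thresholds as *data*: they are transcribed once, never
re-estimated, and every computation is an exact integer sum.

Two structural assumptions follow from the additive form and are
enforced throughout:

* **Non-negative weights imply monotonicity.** Raising any single factor
  to a higher-weight level can never decrease a sub-score. This is
  property-tested over every single-factor perturbation of 1,000
  randomly generated profiles per sub-score.
* **One level per factor.** The sub-score maxima (36 preoperative, 31
  perioperative) are attainable only if exactly one level of each
  categorical factor is scored. Source data sometimes record several
  applicable levels (two concurrent malignancies; an adhesion-count
  grade together with bowel involvement). The engine scores the
  highest-weight applicable level and warns, rather than summing —
  summing would silently push scores past the defined range.

### The factors and their encodings

`ars_weights("preoperative")` and `ars_weights("perioperative")` print
the full factor/level/point dictionary. Points of note:

* **Endometriosis** is consumed as an rASRM stage (`minimal` … `severe`
  for stages I–IV). Computing the stage from lesion maps is out of
  scope: the package scores a stage, it does not derive one.
* **Adhesion severity** uses the classical four extent grades (single;
  2–3; >3; bowel involvement) that have become standard; as with the
  rASRM stage, grading itself happens at the table, not in software.
* **Adhesion quality** has no 1-point level (`filmy` scores 2). The
  table is transcribed as defined, not "corrected".
* **Previous surgeries** score 0/3/4 for none/one/more than one.

### Procedure duration bands

Duration scores 2 points under 90 minutes, 3 points from 90 minutes up
to and including 2 hours, and 4 points over 2 hours. The 120-minute
boundary belongs to the middle band because the top band is defined
strictly as *over* 2 hours. Because these edges are sharp, file input
accepts duration only as a number of minutes — never clock formats such
as `"1h30"` — so a parsing ambiguity can never silently move a patient
across the 3/4-point boundary.

### Cross-field rules

Two clinical consistency rules are validated, not repaired, in patient
data:

* The three *sequelae of previous operations* (intraperitoneal bleeding
  with an unexpected Hb drop of ≥ 2 g%, postoperative complications,
  postoperative infection) are by definition events of a previous
  operation: any of them combined with `previous_surgery_count = 0` is a
  contradiction and invalidates the record.
* `adhesion_quality = "none"` if and only if
  `adhesion_severity = "none"`: absent adhesions have neither a quality
  nor an extent.

`duration_minutes` and `surgery_type_site` are mandatory (every
operation has both; this is what makes 3 the perioperative minimum); all
other factors are optional and default to absent/false — silently in the
programmatic constructors, where the default is explicit in the
signature, and with an aggregated warning in the file readers, where a
missing value may be an oversight.

## Thresholds

The low/medium/high intervals (preoperative 0–12/13–24/25–36,
perioperative 3–17/18–28/29–31) are inclusive at both ends and partition
the achievable ranges exactly. The preoperative cutoffs coincide with
tertiles of the 0–36 range; the perioperative cutoffs deviate from
arithmetic tertiles because they were adjusted after clinical field
testing of the score. The adjusted published values are authoritative
and are the package defaults. `classify()` refuses out-of-range scores
instead of clamping: an out-of-range value can only mean a scoring bug
upstream, and clamping would hide it. A configuration file can override
the intervals for sensitivity exploration, but any override must still
partition the achievable range — gaps or overlaps are rejected.

The total ARS (`total_ars()`, range 3–67) deliberately carries no risk
category: no combined thresholds are defined, and inventing them would
suggest a validation that does not exist.

## The synthetic-cohort generator

No patient-level cohort distribution is published for this score, and
its original small-scale field test is unpublished, so there is nothing
empirical to emulate. The generator (`generate_cohort()`) exists to make
every pipeline stage testable without external data. It draws each
factor **independently** from configurable marginal prevalences
(`prevalence_spec()`), then repairs the two cross-field rules
deterministically, in a fixed order chosen so that identical seed and
spec always reproduce identical cohorts:

1. the surgery count is drawn before the sequelae; with no previous
   surgery the three sequelae are forced to `FALSE`;
2. adhesion quality is drawn before severity; `quality = "none"` forces
   `severity = "none"`, and with existing adhesions a drawn severity of
   `"none"` is raised to the lowest grade, `"single"`.

The default prevalences are invented but deliberately plausible for a
general gynaecological surgical population — e.g. half the patients with
no previous abdominal/pelvic surgery, 70 % without endometriosis, 92 %
without cancer, 45 % of procedures under 90 minutes, electrical scalpel
in 60 % of procedures. They were fixed once as the package's reference
condition and are not tuned. Durations are drawn as whole minutes,
uniformly within the sampled band (30–89 / 90–120 / 121–240 min).
`previous_surgery_count` is drawn over {0, 1, 2} by default since only
three weight bands exist; other counts may be specified.

An optional `correlation` hook (a function transforming the drawn factor
table before repair) can induce dependence between factors — for example
raising adhesion quality in severe endometriosis — but it is off by
default: independence is the honest default in the absence of any
published joint distribution.

**What passing tests do and do not show.** The generator produces
records that are structurally valid and marginally calibrated; it does
not reproduce real-world correlations between risk factors (adhesion
history and adhesion quality are strongly dependent in reality), site-
or surgeon-level clustering, or any association between score and actual
adhesion outcome. Tests on synthetic cohorts therefore verify the
*engine* — weights, sums, thresholds, I/O — not the clinical validity of
the score.

Empirical prevalence convergence is checked on a cohort of 10,000
patients at the two-sided 3-standard-error level per factor (binary
factors by a direct 3 SE band, categorical factors by a Pearson
goodness-of-fit test at the matching significance level, repaired
factors against their post-repair law conditional on eligibility).

## Exhaustive enumeration as oracle

`enumerate_profiles()` lists every combination of declared factor levels
exactly once — 14,400 preoperative and 23,040 perioperative
combinations, with one representative duration per band (60/105/150
min), since the score depends on duration only through its band.
Scoring the full enumeration reproduces the defined extremes exactly
(0–36 and 3–31), shows that every intermediate integer score is
achievable, and bounds the runtime of the whole verification under a
second on one CPU. Combinations violating a cross-field rule are
excluded from the returned set and counted in the `n_excluded`
attribute (4,200 preoperative, 8,064 perioperative); the extremes are
unaffected because the minimum and maximum profiles are both
cross-field-valid.

```{r enumeration}
enum <- enumerate_profiles("perioperative")
c(total = attr(enum, "n_total"), excluded = attr(enum, "n_excluded"))
range(score_cohort(enum, sub_score = "perioperative",
                   validate = FALSE)$perioperative_score)
```

## Numerical and interface choices

* **Integer arithmetic throughout.** Scores, weights and breakdowns are
  R integers; there is no floating-point pathway that could shift a
  threshold decision.
* **Batch validation vs. speed.** `score_cohort()` validates data-frame
  input row by row through the same normaliser as the file readers.
  `validate = FALSE` skips this for inputs that are typed and valid by
  construction (the enumeration, generator output); this is what keeps
  scoring 37,000+ enumerated profiles under a second.
* **Boolean tokens** in files accept `true/false`, `yes/no`, `1/0`
  case-insensitively; enum levels accept the canonical snake-case token
  only. Fuzzy level matching is deliberately absent: silently mapping
  `"Severe?"` to `"severe"` is the kind of convenience that corrupts
  clinical data.
* **Stable column order** in scored output (identifiers, sub-scores,
  categories, total, then the 20 per-factor point columns in canonical
  factor order) so that written files are byte-stable and round-trip
  through `read_results()` exactly.
* **Percentages** in cohort summaries are reported to one decimal; the
  rounding residue is assigned to the largest category so displayed
  percentages always sum to 100.0.
* **Degenerate inputs**: an empty cohort summarises to an explicit
  empty marker and writes a header-only file; a cohort with only one
  profile type reports `NA` for the other sub-score and omits the total.

## Known limitations

* The score is an expert consensus index; the package can verify its
  internal consistency but nothing about its predictive validity — no
  outcome model links score to adhesion probability, so none is
  simulated.
* The weights encode the judgment of one consensus panel at one point
  in time; the package treats them as fixed data and offers no
  re-weighting interface.
* The synthetic generator's independence assumption understates the
  clustering of risk factors in real cohorts; cohort-level summaries on
  synthetic data should not be read as epidemiological estimates.
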