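# Weight tables: per-factor point lookups against the published table.

test_that("ordinal and banded factor lookups return the published points", {
  cases <- list(
    list(weight_previous_surgery, 0, 0L),
    list(weight_previous_surgery, 1, 3L),
    list(weight_previous_surgery, 2, 4L),
    list(weight_previous_surgery, 7, 4L),
    list(weight_endometriosis, "absent", 0L),
    list(weight_endometriosis, "minimal", 1L),
    list(weight_endometriosis, "mild", 2L),
    list(weight_endometriosis, "moderate", 3L),
    list(weight_endometriosis, "severe", 4L),
    list(weight_cancer, "absent", 0L),
    list(weight_cancer, "gynaecologic", 2L),
    list(weight_cancer, "peritoneal_carcinomatosis", 2L),
    list(weight_cancer, "local_non_gynaecological", 3L),
    list(weight_cancer, "metastatic_extrapelvic", 2L),
    list(weight_radiation, "absent", 0L),
    list(weight_radiation, "local", 4L),
    list(weight_radiation, "distant", 1L),
    list(weight_duration, 60, 2L),
    list(weight_duration, 100, 3L),
    list(weight_duration, 180, 4L),
    list(weight_adhesion_quality, "none", 0L),
    list(weight_adhesion_quality, "filmy", 2L),
    list(weight_adhesion_quality, "vascular", 3L),
    list(weight_adhesion_quality, "dense", 4L),
    list(weight_adhesion_severity, "none", 0L),
    list(weight_adhesion_severity, "single", 1L),
    list(weight_adhesion_severity, "two_or_three", 2L),
    list(weight_adhesion_severity, "more_than_three", 3L),
    list(weight_adhesion_severity, "bowel_involvement", 4L),
    list(weight_surgery_type_site, "laparoscopy_fallopian_tube", 1L),
    list(weight_surgery_type_site, "open_uterus", 3L),
    list(weight_surgery_type_site, "open_fallopian_tube", 2L),
    list(weight_surgery_type_site, "laparoscopy_adhesiolysis_uterus", 3L),
    list(weight_surgery_type_site, "laparoscopy_other", 2L),
    list(weight_surgery_type_site, "open_ovary", 4L)
  )
  for (case in cases) {
    expect_identical(case[[1]](case[[2]]), case[[3]],
                     label = sprintf("weight(%s)", format(case[[2]])))
  }
})

test_that("duration band boundaries: 90 and 120 min fall in the middle band", {
  expect_identical(weight_duration(c(89, 89.9, 90, 120, 120.1, 121)),
                   c(2L, 2L, 3L, 3L, 4L, 4L))
})

test_that("invalid lookup inputs raise validation errors", {
  expect_error(weight_previous_surgery(-1), "non-negative")
  expect_error(weight_previous_surgery(1.5), "whole number")
  expect_error(weight_endometriosis("extreme"), "invalid endometriosis")
  expect_error(weight_cancer("lymphoma"), "invalid cancer")
  expect_error(weight_duration(0), "positive")
  expect_error(weight_duration(-30), "positive")
  expect_error(weight_adhesion_severity("many"), "invalid adhesion_severity")
  expect_error(weight_surgery_type_site("open_bowel"),
               "invalid surgery_type_site")
})

test_that("weight tables are complete, bounded in 0..4, with published column maxima", {
  for (kind in c("preoperative", "perioperative")) {
    tab <- ars_weights(kind)
    expect_true(all(tab$points %in% 0:4))
    expect_identical(length(unique(tab$factor)), 10L)
    # every declared level has exactly one entry
    expect_false(any(duplicated(tab[c("factor", "level")])))
  }
  per_factor_max <- function(kind) {
    tab <- ars_weights(kind)
    tapply(tab$points, tab$factor, max)
  }
  expect_identical(sum(per_factor_max("preoperative")), 36L)
  expect_identical(sum(per_factor_max("perioperative")), 31L)
})

test_that("binary factors score their published weight when present, 0 when absent", {
  pre_weights <- c(
    history_postsurgical_adhesions = 4L,
    concomitant_inflammation_or_infection = 4L,
    keloid_scarring = 3L
  )
  for (f in names(pre_weights)) {
    args <- stats::setNames(list(TRUE), f)
    sc <- do.call(preoperative_profile, args)
    expect_identical(score_preoperative(sc)$score, pre_weights[[f]])
  }
  # sequelae of previous operations need a previous operation to be scored
  seq_weights <- c(
    prior_intraperitoneal_bleeding = 2L,
    prior_postoperative_complications = 4L,
    prior_postoperative_infection = 4L
  )
  for (f in names(seq_weights)) {
    args <- c(stats::setNames(list(TRUE), f),
              list(previous_surgery_count = 1))
    sc <- score_preoperative(do.call(preoperative_profile, args))
    expect_identical(sc$score, seq_weights[[f]] + 3L)  # + one prior surgery
    expect_identical(sc$breakdown[[f]], seq_weights[[f]])
  }
  peri_weights <- c(
    bleeding_over_500ml = 4L, complex_or_multiquadrant = 3L,
    excessive_coagulation = 2L, foreign_body_placement = 3L,
    electrical_scalpel = 2L, peritoneal_closing = 1L
  )
  for (f in names(peri_weights)) {
    sc <- score_perioperative(do.call(
      min_perioperative_profile, stats::setNames(list(TRUE), f)))
    expect_identical(sc$score, peri_weights[[f]] + 3L)
    expect_identical(sc$breakdown[[f]], peri_weights[[f]])
  }
})

test_that("profiles validate enum levels and cross-field rules", {
  expect_error(preoperative_profile(endometriosis = "extreme"),
               "endometriosis")
  expect_error(preoperative_profile(previous_surgery_count = -2),
               "non-negative")
  # sequelae without any previous operation are contradictory
  expect_error(
    preoperative_profile(prior_postoperative_infection = TRUE),
    "at least one previous operation"
  )
  expect_silent(
    preoperative_profile(previous_surgery_count = 1,
                         prior_postoperative_infection = TRUE)
  )
  # mandatory perioperative fields
  expect_error(perioperative_profile(surgery_type_site = "open_uterus"),
               "duration_minutes")
  expect_error(perioperative_profile(duration_minutes = 60),
               "surgery_type_site")
  expect_error(
    perioperative_profile(duration_minutes = 0,
                          surgery_type_site = "open_uterus"),
    "positive")
  # no adhesions means both quality and severity report none
  expect_error(min_perioperative_profile(adhesion_severity = "single"),
               "adhesion_quality = 'none'")
  expect_error(min_perioperative_profile(adhesion_quality = "filmy"),
               "severity grade")
})

test_that("multiple applicable levels score the highest-weight one with a warning", {
  expect_warning(
    p <- preoperative_profile(
      cancer = c("gynaecologic", "local_non_gynaecological")),
    "highest-weight"
  )
  expect_identical(p$cancer, "local_non_gynaecological")
  expect_identical(score_preoperative(p)$breakdown[["cancer"]], 3L)
  # a count category together with bowel involvement: bowel involvement wins
  expect_warning(
    q <- min_perioperative_profile(
      adhesion_quality = "filmy",
      adhesion_severity = c("two_or_three", "bowel_involvement")),
    "highest-weight"
  )
  expect_identical(q$adhesion_severity, "bowel_involvement")
  # factors that are genuinely single-valued reject multiple levels
  expect_error(preoperative_profile(endometriosis = c("mild", "severe")),
               "single level")
})
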