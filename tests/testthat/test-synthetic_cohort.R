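# Synthetic cohorts and the exhaustive enumeration oracle.

test_that("enumeration covers every level combination once, excluding cross-field-invalid ones", {
  pre <- enumerate_profiles("preoperative")
  # 3 x 2 x 2 x 5 x 5 x 3 x 2 x 2 x 2 x 2 combinations
  expect_identical(attr(pre, "n_total"), 14400L)
  # count = 0 forbids the three sequelae: 4800 * 7/8 combinations drop out
  expect_identical(attr(pre, "n_excluded"), 4200L)
  expect_identical(nrow(pre), 10200L)
  expect_false(any(duplicated(pre)))

  peri <- enumerate_profiles("perioperative")
  # 4 x 5 x 2 x 3 x 2 x 2 x 6 x 2 x 2 x 2 combinations
  expect_identical(attr(peri, "n_total"), 23040L)
  # 13 of the 20 quality x severity pairs agree on adhesion presence
  expect_identical(nrow(peri), (23040L * 13L) %/% 20L)
  expect_identical(attr(peri, "n_excluded") + nrow(peri),
                   attr(peri, "n_total"))
  expect_false(any(duplicated(peri)))
})

test_that("enumeration + scoring reproduces the printed extremes and full achievable sets", {
  pre_scores <- score_cohort(enumerate_profiles("preoperative"),
                             sub_score = "preoperative",
                             validate = FALSE)$preoperative_score
  expect_identical(min(pre_scores), 0L)
  expect_identical(max(pre_scores), 36L)
  # every intermediate integer score is achievable
  expect_identical(sort(unique(pre_scores)), 0:36)

  peri_scores <- score_cohort(enumerate_profiles("perioperative"),
                              sub_score = "perioperative",
                              validate = FALSE)$perioperative_score
  expect_identical(min(peri_scores), 3L)
  expect_identical(max(peri_scores), 31L)
  expect_identical(sort(unique(peri_scores)), 3:31)
})

test_that("same seed and spec give identical cohorts; different seeds differ", {
  a <- generate_cohort(50, seed = 123)
  b <- generate_cohort(50, seed = 123)
  expect_identical(a, b)
  c <- generate_cohort(50, seed = 124)
  expect_false(identical(a, c))
  # the caller's RNG state is untouched
  set.seed(99)
  before <- .Random.seed
  invisible(generate_cohort(10, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("degenerate prevalence specs yield the published extreme cohorts", {
  lo <- score_cohort(generate_cohort(50, minimum_prevalence_spec(),
                                     seed = 1))
  expect_true(all(lo$preoperative_score == 0L))
  expect_true(all(lo$perioperative_score == 3L))
  hi <- score_cohort(generate_cohort(50, maximum_prevalence_spec(),
                                     seed = 1))
  expect_true(all(hi$preoperative_score == 36L))
  expect_true(all(hi$perioperative_score == 31L))
})

test_that("every generated record passes validation with an empty report", {
  coh <- generate_cohort(200, seed = 7)
  reports <- lapply(coh$records, validate_record)
  expect_true(all(vapply(reports, nrow, integer(1L)) == 0L))
})

test_that("empirical prevalences converge to the spec at n = 10000", {
  n <- 10000L
  spec <- prevalence_spec()
  coh <- generate_cohort(n, spec, seed = 2024)
  field_col <- function(f) {
    kind <- if (f %in% names(coh$records[[1]]$preoperative)) "preoperative"
            else "perioperative"
    sapply(coh$records, function(r) r[[kind]][[f]])
  }
  fields <- c(names(coh$records[[1]]$preoperative),
              names(coh$records[[1]]$perioperative))
  df <- as.data.frame(stats::setNames(lapply(fields, field_col), fields),
                      stringsAsFactors = FALSE)
  # unrepaired binary factors: marginal prevalence
  for (f in c("history_postsurgical_adhesions",
              "concomitant_inflammation_or_infection", "keloid_scarring",
              "bleeding_over_500ml", "complex_or_multiquadrant",
              "excessive_coagulation", "foreign_body_placement",
              "electrical_scalpel", "peritoneal_closing")) {
    expect_true(within_3se(mean(df[[f]]), spec[[f]], n), label = f)
  }
  # repaired sequelae: prevalence conditional on having a previous operation
  prior <- df$previous_surgery_count >= 1L
  for (f in c("prior_intraperitoneal_bleeding",
              "prior_postoperative_complications",
              "prior_postoperative_infection")) {
    expect_true(within_3se(mean(df[[f]][prior]), spec[[f]], sum(prior)),
                label = f)
  }
  # categorical factors: per-factor goodness of fit
  for (f in c("endometriosis", "cancer", "radiation", "adhesion_quality",
              "surgery_type_site")) {
    expect_true(
      gof_ok(level_counts(df[[f]], names(spec[[f]])), spec[[f]]),
      label = f
    )
  }
  # repaired severity: among patients with adhesions the drawn "none" mass
  # moves deterministically to "single"
  with_adh <- df$adhesion_quality != "none"
  sev_expect <- spec$adhesion_severity
  sev_expect[["single"]] <- sev_expect[["single"]] + sev_expect[["none"]]
  sev_expect[["none"]] <- 0
  expect_true(gof_ok(
    level_counts(df$adhesion_severity[with_adh], names(sev_expect)),
    sev_expect))
  expect_false(any(df$adhesion_severity[with_adh] == "none"))
  # previous surgery counts
  expect_true(gof_ok(
    level_counts(as.character(df$previous_surgery_count),
                 names(spec$previous_surgery_count)),
    spec$previous_surgery_count))
  # duration bands
  band <- cut(df$duration_minutes, c(0, 90, 121, Inf), right = FALSE,
              labels = c("short", "medium", "long"))
  expect_true(gof_ok(level_counts(band, names(spec$duration_band)),
                     spec$duration_band))
})

test_that("prevalence specs are validated", {
  expect_error(prevalence_spec(keloid_scarring = 1.2), "\\[0, 1\\]")
  expect_error(prevalence_spec(endometriosis = c(absent = 0.5, mild = 0.4)),
               "sum to 1")
  expect_error(prevalence_spec(endometriosis = c(nonlevel = 1)),
               "unknown endometriosis")
  expect_error(prevalence_spec(nonsense = 0.5), "unknown prevalence")
  expect_error(generate_cohort(0), "positive integer")
})

test_that("the correlation hook induces dependence and records stay valid", {
  hook <- function(df) {
    sev <- df$endometriosis == "severe"
    df$adhesion_quality[sev] <- "dense"
    df
  }
  spec <- prevalence_spec(
    endometriosis = c(absent = 0.5, severe = 0.5),
    correlation = hook
  )
  coh <- generate_cohort(300, spec, seed = 3)
  df <- data.frame(
    endometriosis = sapply(coh$records,
                           function(r) r$preoperative$endometriosis),
    adhesion_quality = sapply(coh$records,
                              function(r) r$perioperative$adhesion_quality),
    stringsAsFactors = FALSE
  )
  expect_true(all(df$adhesion_quality[df$endometriosis == "severe"] ==
                    "dense"))
  # repair still enforces quality/severity agreement
  reports <- lapply(coh$records, validate_record)
  expect_true(all(vapply(reports, nrow, integer(1L)) == 0L))
})
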