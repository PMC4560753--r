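# Sub-score computation, classification and the total ARS.

test_that("the published extreme profiles reproduce the printed totals", {
  sc_min <- score_preoperative(preoperative_profile())
  expect_identical(sc_min$score, 0L)
  expect_identical(sc_min$risk_category, "low")
  sc_max <- score_preoperative(max_preoperative_profile())
  expect_identical(sc_max$score, 36L)
  expect_identical(sc_max$risk_category, "high")
  sc_pmin <- score_perioperative(min_perioperative_profile())
  expect_identical(sc_pmin$score, 3L)
  expect_identical(sc_pmin$risk_category, "low")
  sc_pmax <- score_perioperative(max_perioperative_profile())
  expect_identical(sc_pmax$score, 31L)
  expect_identical(sc_pmax$risk_category, "high")
})

test_that("breakdowns have one entry per factor and sum to the score", {
  for (sc in list(score_preoperative(max_preoperative_profile()),
                  score_perioperative(max_perioperative_profile()),
                  score_preoperative(preoperative_profile(
                    endometriosis = "mild", cancer = "gynaecologic")))) {
    expect_length(sc$breakdown, 10L)
    expect_identical(sum(sc$breakdown), sc$score)
    expect_true(all(sc$breakdown %in% 0:4))
  }
})

test_that("single-factor profiles score exactly that factor's weight", {
  sc <- score_preoperative(
    preoperative_profile(history_postsurgical_adhesions = TRUE))
  expect_identical(sc$score, 4L)
  expect_identical(unname(sc$breakdown[sc$breakdown > 0]), 4L)
  # minimal operation plus an electrical scalpel: 3 + 2
  sc2 <- score_perioperative(
    min_perioperative_profile(electrical_scalpel = TRUE))
  expect_identical(sc2$score, 5L)
})

test_that("classification is exact at all six published boundaries", {
  expect_identical(classify(c(0, 12, 13, 24, 25, 36), "preoperative"),
                   c("low", "low", "medium", "medium", "high", "high"))
  expect_identical(classify(c(3, 17, 18, 28, 29, 31), "perioperative"),
                   c("low", "low", "medium", "medium", "high", "high"))
})

test_that("classification is total and exclusive over the achievable ranges", {
  pre <- classify(0:36, "preoperative")
  expect_identical(as.integer(table(factor(pre, c("low", "medium", "high")))),
                   c(13L, 12L, 12L))
  peri <- classify(3:31, "perioperative")
  expect_identical(as.integer(table(factor(peri, c("low", "medium", "high")))),
                   c(15L, 11L, 3L))
  # no gaps: every score got exactly one category
  expect_false(anyNA(pre))
  expect_false(anyNA(peri))
})

test_that("out-of-range scores are an error, never clamped", {
  expect_error(classify(37, "preoperative"), "outside the achievable")
  expect_error(classify(-1, "preoperative"), "outside the achievable")
  expect_error(classify(2, "perioperative"), "outside the achievable")
  expect_error(classify(32, "perioperative"), "outside the achievable")
})

test_that("the intraoperative alias names the perioperative sub-score", {
  expect_identical(classify(29, "intraoperative"), "high")
  expect_identical(attr(enumerate_profiles("intraoperative"), "n_total"),
                   attr(enumerate_profiles("perioperative"), "n_total"))
})

test_that("custom thresholds must partition the achievable range", {
  th <- ars_thresholds()
  th$upper[th$sub_score == "preoperative" & th$risk == "low"] <- 10L
  expect_error(classify(5, "preoperative", thresholds = th), "no gaps")
  th$lower[th$sub_score == "preoperative" & th$risk == "medium"] <- 11L
  expect_identical(classify(c(10, 11), "preoperative", thresholds = th),
                   c("low", "medium"))
})

test_that("total ARS is the plain sum of the sub-scores and carries no category", {
  pre0 <- score_preoperative(preoperative_profile())
  peri3 <- score_perioperative(min_perioperative_profile())
  expect_identical(total_ars(pre0, peri3), 3L)
  t_max <- total_ars(score_preoperative(max_preoperative_profile()),
                     score_perioperative(max_perioperative_profile()))
  expect_identical(t_max, 67L)
  expect_null(attr(t_max, "risk_category"))
  expect_true(is.integer(t_max) && length(t_max) == 1L)
  expect_error(total_ars(peri3, pre0), "one preoperative and one perioperative")
  expect_error(total_ars(pre0, pre0), "one preoperative and one perioperative")
})

test_that("batch scoring agrees with single-profile scoring", {
  coh <- generate_cohort(40, seed = 11)
  scored <- score_cohort(coh)
  for (i in c(1L, 7L, 40L)) {
    r <- coh$records[[i]]
    expect_identical(scored$preoperative_score[i],
                     score_preoperative(r$preoperative)$score)
    expect_identical(scored$perioperative_score[i],
                     score_perioperative(r$perioperative)$score)
  }
  expect_identical(scored$total_ars,
                   scored$preoperative_score + scored$perioperative_score)
})
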