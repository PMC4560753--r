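# Property-test machinery: factor-level dictionaries with weight accessors
# (via the exported lookup functions) and a vectorised monotonicity check.

cohort_factor_df <- function(coh, kind) {
  fields <- names(coh$records[[1]][[kind]])
  cols <- lapply(fields, function(f) {
    sapply(coh$records, function(r) r[[kind]][[f]])
  })
  as.data.frame(stats::setNames(cols, fields), stringsAsFactors = FALSE)
}

# per-factor candidate levels and a weight accessor; boolean factors use
# the 0/1 proxy (their weight when present is positive, so presence always
# weighs more than absence)
factor_level_specs <- function(kind) {
  bool <- list(levels = c(FALSE, TRUE),
               weight_of = function(v) as.integer(v))
  if (kind == "preoperative") {
    list(
      previous_surgery_count = list(
        levels = c(0L, 1L, 2L), weight_of = weight_previous_surgery),
      history_postsurgical_adhesions = bool,
      concomitant_inflammation_or_infection = bool,
      endometriosis = list(
        levels = c("absent", "minimal", "mild", "moderate", "severe"),
        weight_of = weight_endometriosis),
      cancer = list(
        levels = c("absent", "gynaecologic", "peritoneal_carcinomatosis",
                   "local_non_gynaecological", "metastatic_extrapelvic"),
        weight_of = weight_cancer),
      radiation = list(
        levels = c("absent", "local", "distant"),
        weight_of = weight_radiation),
      keloid_scarring = bool,
      prior_intraperitoneal_bleeding = bool,
      prior_postoperative_complications = bool,
      prior_postoperative_infection = bool
    )
  } else {
    list(
      adhesion_quality = list(
        levels = c("none", "filmy", "vascular", "dense"),
        weight_of = weight_adhesion_quality),
      adhesion_severity = list(
        levels = c("none", "single", "two_or_three", "more_than_three",
                   "bowel_involvement"),
        weight_of = weight_adhesion_severity),
      bleeding_over_500ml = bool,
      duration_minutes = list(
        levels = c(60, 105, 150), weight_of = weight_duration),
      complex_or_multiquadrant = bool,
      excessive_coagulation = bool,
      surgery_type_site = list(
        levels = c("laparoscopy_fallopian_tube", "open_uterus",
                   "open_fallopian_tube", "laparoscopy_adhesiolysis_uterus",
                   "laparoscopy_other", "open_ovary"),
        weight_of = weight_surgery_type_site),
      foreign_body_placement = bool,
      electrical_scalpel = bool,
      peritoneal_closing = bool
    )
  }
}

# Per-factor prevalence convergence at the two-sided 3-sigma level:
# binary factors by |phat - p| <= 3 SE, categorical factors by a Pearson
# goodness-of-fit test at the matching alpha.
within_3se <- function(obs, p, m) {
  abs(obs - p) <= 3 * sqrt(p * (1 - p) / m) + 1e-12
}

gof_alpha3 <- 2 * stats::pnorm(-3)

gof_ok <- function(counts, probs) {
  keep <- probs > 0
  if (any(counts[!keep] > 0)) return(FALSE)  # impossible levels occurred
  counts <- counts[keep]
  probs <- probs[keep]
  if (length(probs) < 2L) return(TRUE)
  p <- suppressWarnings(
    stats::chisq.test(counts, p = probs / sum(probs))$p.value)
  p >= gof_alpha3
}

level_counts <- function(values, levels) {
  as.integer(table(factor(values, levels = levels)))
}

# number of monotonicity violations over all single-factor perturbations
# of the profiles in `df` (perturbations to levels of weight >= current)
count_monotonicity_violations <- function(df, kind) {
  score_col <- paste0(kind, "_score")
  base <- score_cohort(df, sub_score = kind,
                       validate = FALSE)[[score_col]]
  violations <- 0L
  for (f in names(factor_level_specs(kind))) {
    spec <- factor_level_specs(kind)[[f]]
    curw <- spec$weight_of(df[[f]])
    for (j in seq_along(spec$levels)) {
      df2 <- df
      df2[[f]] <- rep(spec$levels[j], nrow(df))
      news <- score_cohort(df2, sub_score = kind,
                           validate = FALSE)[[score_col]]
      raised <- spec$weight_of(spec$levels[j]) >= curw
      violations <- violations + sum(news[raised] < base[raised])
    }
  }
  violations
}
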