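# Synthetic cohorts and exhaustive profile enumeration.
#
# No patient-level cohort distribution is published for this score, so the
# generator draws each factor independently from configurable marginal
# prevalences (invented, plausible defaults for a general gynaecological
# surgical population; see the methods vignette) and then repairs the two
# cross-field rules in a fixed, seed-stable order.

.default_prevalence <- function() {
  list(
    previous_surgery_count = c("0" = 0.50, "1" = 0.30, "2" = 0.20),
    history_postsurgical_adhesions = 0.15,
    concomitant_inflammation_or_infection = 0.10,
    endometriosis = c(absent = 0.70, minimal = 0.10, mild = 0.08,
                      moderate = 0.07, severe = 0.05),
    cancer = c(absent = 0.92, gynaecologic = 0.04,
               peritoneal_carcinomatosis = 0.01,
               local_non_gynaecological = 0.02,
               metastatic_extrapelvic = 0.01),
    radiation = c(absent = 0.95, local = 0.03, distant = 0.02),
    keloid_scarring = 0.05,
    prior_intraperitoneal_bleeding = 0.05,
    prior_postoperative_complications = 0.08,
    prior_postoperative_infection = 0.08,
    adhesion_quality = c(none = 0.55, filmy = 0.20, vascular = 0.15,
                         dense = 0.10),
    adhesion_severity = c(none = 0.55, single = 0.15, two_or_three = 0.15,
                          more_than_three = 0.10, bowel_involvement = 0.05),
    bleeding_over_500ml = 0.07,
    duration_band = c(short = 0.45, medium = 0.30, long = 0.25),
    complex_or_multiquadrant = 0.15,
    excessive_coagulation = 0.20,
    surgery_type_site = c(laparoscopy_fallopian_tube = 0.10,
                          open_uterus = 0.15, open_fallopian_tube = 0.05,
                          laparoscopy_adhesiolysis_uterus = 0.15,
                          laparoscopy_other = 0.40, open_ovary = 0.15),
    foreign_body_placement = 0.10,
    electrical_scalpel = 0.60,
    peritoneal_closing = 0.30
  )
}

.boolean_prev_fields <- c(
  names(.default_prevalence())[vapply(.default_prevalence(), length,
                                      integer(1L)) == 1L]
)

# duration (minutes) sampled uniformly on integers within each band
.duration_band_minutes <- list(
  short = 30:89, medium = 90:120, long = 121:240
)

#' Prevalence specification for the synthetic-cohort generator
#'
#' Defines the marginal distribution of every risk factor: a single
#' probability for each binary factor, and a named probability vector over
#' levels for ordinal/categorical factors. `previous_surgery_count` is a
#' probability vector over counts (default over 0/1/2, since only three
#' weight bands exist; other counts may be named). `duration_band` is a
#' probability vector over `short` (under 90 min), `medium` (90-120 min)
#' and `long` (over 120 min); the generator then draws a whole-minute
#' duration uniformly within the band. Probability vectors may name a
#' subset of levels; unnamed levels get probability 0. Degenerate (0/1)
#' probabilities are allowed, so extreme cohorts can be generated for
#' testing.
#'
#' @param ... Named overrides of the default prevalences (see
#'   [generate_cohort()] examples).
#' @param correlation Optional hook: a function taking and returning the
#'   wide factor data frame, applied after the independent draws and
#'   before cross-field repair, to induce dependence between factors (for
#'   example raising adhesion quality in severe endometriosis). Off by
#'   default; independence between factors is the default generative
#'   assumption.
#' @return An object of class `prevalence_spec`.
#' @examples
#' prevalence_spec(endometriosis = c(absent = 0.5, severe = 0.5))
#' @export
prevalence_spec <- function(..., correlation = NULL) {
  spec <- .default_prevalence()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) {
    stop("unknown prevalence field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(dots)) spec[[nm]] <- dots[[nm]]

  for (nm in names(spec)) {
    p <- spec[[nm]]
    if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
      stop("prevalence for ", nm, " must be probabilities in [0, 1]",
           call. = FALSE)
    }
    if (nm %in% .boolean_prev_fields) {
      if (length(p) != 1L) {
        stop("prevalence for binary factor ", nm,
             " must be a single probability", call. = FALSE)
      }
    } else {
      levels <- if (nm == "previous_surgery_count") NULL
        else if (nm == "duration_band") names(.duration_band_minutes)
        else names(.ars_enum_points[[nm]])
      if (is.null(names(p)) || any(!nzchar(names(p)))) {
        stop("prevalence vector for ", nm, " must be named", call. = FALSE)
      }
      if (nm == "previous_surgery_count") {
        counts <- suppressWarnings(as.integer(names(p)))
        if (anyNA(counts) || any(counts < 0)) {
          stop("previous_surgery_count prevalences must be named by ",
               "non-negative counts", call. = FALSE)
        }
      } else if (!all(names(p) %in% levels)) {
        stop("unknown ", nm, " level(s): ",
             paste(setdiff(names(p), levels), collapse = ", "),
             call. = FALSE)
      }
      if (abs(sum(p) - 1) > 1e-9) {
        stop("prevalence vector for ", nm, " must sum to 1 (got ",
             format(sum(p)), ")", call. = FALSE)
      }
    }
  }
  if (!is.null(correlation) && !is.function(correlation)) {
    stop("`correlation` must be NULL or a function", call. = FALSE)
  }
  structure(c(spec, list(correlation = correlation)),
            class = "prevalence_spec")
}

#' Prevalence specification of the minimum-risk cohort
#'
#' Every factor at its lowest level and every optional factor absent: all
#' patients score 0 preoperatively and 3 perioperatively (the achievable
#' minima).
#'
#' @return A `prevalence_spec`.
#' @export
minimum_prevalence_spec <- function() {
  prevalence_spec(
    previous_surgery_count = c("0" = 1),
    history_postsurgical_adhesions = 0,
    concomitant_inflammation_or_infection = 0,
    endometriosis = c(absent = 1),
    cancer = c(absent = 1),
    radiation = c(absent = 1),
    keloid_scarring = 0,
    prior_intraperitoneal_bleeding = 0,
    prior_postoperative_complications = 0,
    prior_postoperative_infection = 0,
    adhesion_quality = c(none = 1),
    adhesion_severity = c(none = 1),
    bleeding_over_500ml = 0,
    duration_band = c(short = 1),
    complex_or_multiquadrant = 0,
    excessive_coagulation = 0,
    surgery_type_site = c(laparoscopy_fallopian_tube = 1),
    foreign_body_placement = 0,
    electrical_scalpel = 0,
    peritoneal_closing = 0
  )
}

#' Prevalence specification of the maximum-risk cohort
#'
#' Every factor at its highest-weight level: all patients score 36
#' preoperatively and 31 perioperatively (the achievable maxima).
#'
#' @return A `prevalence_spec`.
#' @export
maximum_prevalence_spec <- function() {
  prevalence_spec(
    previous_surgery_count = c("2" = 1),
    history_postsurgical_adhesions = 1,
    concomitant_inflammation_or_infection = 1,
    endometriosis = c(severe = 1),
    cancer = c(local_non_gynaecological = 1),
    radiation = c(local = 1),
    keloid_scarring = 1,
    prior_intraperitoneal_bleeding = 1,
    prior_postoperative_complications = 1,
    prior_postoperative_infection = 1,
    adhesion_quality = c(dense = 1),
    adhesion_severity = c(bowel_involvement = 1),
    bleeding_over_500ml = 1,
    duration_band = c(long = 1),
    complex_or_multiquadrant = 1,
    excessive_coagulation = 1,
    surgery_type_site = c(open_ovary = 1),
    foreign_body_placement = 1,
    electrical_scalpel = 1,
    peritoneal_closing = 1
  )
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  expr
}

#' Generate a seeded synthetic patient cohort
#'
#' Draws `n` complete patient records (both profiles) independently from
#' the marginal prevalences in `spec`, then repairs the cross-field rules
#' deterministically and in a fixed order so that identical `seed` and
#' `spec` always produce an identical cohort:
#'
#' * the surgery count is drawn first; in patients with no previous
#'   surgery the three prior-operation sequelae are forced to `FALSE`;
#' * adhesion quality is drawn first; with no adhesions
#'   (`quality = "none"`) severity is forced to `"none"`, and with
#'   existing adhesions a drawn severity of `"none"` is raised to the
#'   lowest grade `"single"`.
#'
#' Every generated record passes [validate_record()] cleanly.
#'
#' @param n Number of patients (positive integer).
#' @param spec A [prevalence_spec()].
#' @param seed Integer seed; the caller's random-number state is left
#'   untouched. `NULL` uses (and advances) the current state.
#' @return An `ars_cohort` (see [read_cohort()]) of `n` records with
#'   patient identifiers `"S0001"`-style.
#' @examples
#' coh <- generate_cohort(5, seed = 42)
#' score_cohort(coh)[, c("patient_id", "preoperative_score",
#'                       "perioperative_score")]
#' @export
generate_cohort <- function(n, spec = prevalence_spec(), seed = NULL) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n < 1 ||
      n != trunc(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!inherits(spec, "prevalence_spec")) {
    stop("`spec` must be a prevalence_spec()", call. = FALSE)
  }
  n <- as.integer(n)
  .with_seed(seed, {
    draw_levels <- function(p) {
      if (length(p) == 1L) rep(names(p), n)
      else sample(names(p), n, replace = TRUE, prob = p)
    }
    df <- data.frame(
      patient_id = sprintf("S%0*d", max(4L, nchar(n)), seq_len(n)),
      stringsAsFactors = FALSE
    )
    # draw in fixed field order (count before sequelae, quality before
    # severity) so repairs are reproducible across runs
    df$previous_surgery_count <-
      as.integer(draw_levels(spec$previous_surgery_count))
    for (f in names(.ars_binary_points$preoperative)) {
      df[[f]] <- stats::runif(n) < spec[[f]]
    }
    for (f in c("endometriosis", "cancer", "radiation")) {
      df[[f]] <- draw_levels(spec[[f]])
    }
    df$adhesion_quality <- draw_levels(spec$adhesion_quality)
    df$adhesion_severity <- draw_levels(spec$adhesion_severity)
    band <- draw_levels(spec$duration_band)
    df$duration_minutes <- vapply(band, function(b) {
      mins <- .duration_band_minutes[[b]]
      as.numeric(mins[sample.int(length(mins), 1L)])
    }, numeric(1L))
    df$surgery_type_site <- draw_levels(spec$surgery_type_site)
    for (f in names(.ars_binary_points$perioperative)) {
      df[[f]] <- stats::runif(n) < spec[[f]]
    }

    if (!is.null(spec$correlation)) {
      df <- spec$correlation(df)
      if (!is.data.frame(df) || nrow(df) != n) {
        stop("the correlation hook must return the cohort data frame ",
             "unchanged in shape", call. = FALSE)
      }
    }

    # deterministic cross-field repair
    no_surg <- df$previous_surgery_count == 0L
    for (f in .preop_sequelae) df[[f]][no_surg] <- FALSE
    df$adhesion_severity[df$adhesion_quality == "none"] <- "none"
    fix <- df$adhesion_quality != "none" & df$adhesion_severity == "none"
    df$adhesion_severity[fix] <- "single"

    records <- lapply(seq_len(n), function(i) {
      structure(
        list(
          patient_id = df$patient_id[i],
          preoperative = .new_profile(
            "preoperative",
            as.list(df[i, .preop_fields, drop = FALSE])),
          perioperative = .new_profile(
            "perioperative",
            as.list(df[i, .periop_fields, drop = FALSE]))
        ),
        class = "cohort_record"
      )
    })
    .new_ars_cohort(records, .issue_df(), n)
  })
}

#' Exhaustively enumerate all profile-level combinations
#'
#' Enumerates every combination of declared factor levels for one
#' sub-score, exactly once — the brute-force oracle behind the published
#' score ranges (preoperative 0-36, perioperative 3-31). Counts (for
#' previous surgeries) are enumerated over 0/1/2, covering all three
#' weight bands; procedure duration is enumerated by one representative
#' duration per band (60, 105, 150 minutes), since the score depends on
#' duration only through its band.
#'
#' Combinations violating a cross-field rule (prior-operation sequelae
#' without a previous operation; adhesion quality and severity
#' disagreeing on the presence of adhesions) are excluded from the
#' returned set and counted in the attributes.
#'
#' @param sub_score `"preoperative"` or `"perioperative"` (alias
#'   `"intraoperative"`).
#' @return A typed data frame with one column per factor and one row per
#'   valid combination, with attributes `n_total` (combinations before
#'   cross-field exclusion, i.e. the product of the level counts) and
#'   `n_excluded`. Ready for `score_cohort(..., validate = FALSE)`.
#' @examples
#' enum <- enumerate_profiles("preoperative")
#' attr(enum, "n_total")     # 14400 combinations
#' range(score_cohort(enum, sub_score = "preoperative",
#'                    validate = FALSE)$preoperative_score)
#' @export
enumerate_profiles <- function(sub_score = c("preoperative",
                                             "perioperative")) {
  kind <- .match_kind(sub_score[[1L]])
  if (kind == "preoperative") {
    grid <- expand.grid(
      previous_surgery_count = c(0L, 1L, 2L),
      history_postsurgical_adhesions = c(FALSE, TRUE),
      concomitant_inflammation_or_infection = c(FALSE, TRUE),
      endometriosis = names(.ars_enum_points$endometriosis),
      cancer = names(.ars_enum_points$cancer),
      radiation = names(.ars_enum_points$radiation),
      keloid_scarring = c(FALSE, TRUE),
      prior_intraperitoneal_bleeding = c(FALSE, TRUE),
      prior_postoperative_complications = c(FALSE, TRUE),
      prior_postoperative_infection = c(FALSE, TRUE),
      stringsAsFactors = FALSE,
      KEEP.OUT.ATTRS = FALSE
    )
    valid <- !(grid$previous_surgery_count == 0L &
                 (grid$prior_intraperitoneal_bleeding |
                    grid$prior_postoperative_complications |
                    grid$prior_postoperative_infection))
  } else {
    grid <- expand.grid(
      adhesion_quality = names(.ars_enum_points$adhesion_quality),
      adhesion_severity = names(.ars_enum_points$adhesion_severity),
      bleeding_over_500ml = c(FALSE, TRUE),
      duration_minutes = c(60, 105, 150),
      complex_or_multiquadrant = c(FALSE, TRUE),
      excessive_coagulation = c(FALSE, TRUE),
      surgery_type_site = names(.ars_enum_points$surgery_type_site),
      foreign_body_placement = c(FALSE, TRUE),
      electrical_scalpel = c(FALSE, TRUE),
      peritoneal_closing = c(FALSE, TRUE),
      stringsAsFactors = FALSE,
      KEEP.OUT.ATTRS = FALSE
    )
    valid <- (grid$adhesion_quality == "none") ==
      (grid$adhesion_severity == "none")
  }
  out <- grid[valid, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(grid)
  attr(out, "n_excluded") <- sum(!valid)
  out
}
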