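# Scoring engine: sums per-factor points into the two sub-scores,
# classifies them, and batch-scores whole cohorts.

.new_ars_score <- function(kind, breakdown, thresholds = NULL) {
  score <- as.integer(sum(breakdown))
  structure(
    list(
      sub_score = kind,
      score = score,
      breakdown = breakdown,
      risk_category = classify(score, kind, thresholds)
    ),
    class = "ars_score"
  )
}

.profile_breakdown <- function(kind, profile) {
  fields <- .kind_fields(kind)
  vapply(fields, function(f) .factor_points(kind, f, profile[[f]]),
         integer(1L))
}

#' Score the preoperative risk-factor profile
#'
#' Sums the ten preoperative factor points into the Preoperative Adhesion
#' Risk Score (0-36) and classifies it as low (0-12), medium (13-24) or
#' high (25-36) risk.
#'
#' @param profile A [preoperative_profile()] (or a named list coercible to
#'   one).
#' @param thresholds Optional custom threshold table (see
#'   [ars_thresholds()]).
#' @return An object of class `ars_score`: a list with elements
#'   `sub_score`, `score`, `breakdown` (named integer vector of the ten
#'   per-factor points, summing to `score`), and `risk_category`.
#' @examples
#' score_preoperative(preoperative_profile(previous_surgery_count = 1,
#'                                         endometriosis = "moderate"))
#' @export
score_preoperative <- function(profile, thresholds = NULL) {
  if (!inherits(profile, "preoperative_profile")) {
    profile <- .profile_from_raw("preoperative", as.list(profile))
  }
  .new_ars_score("preoperative", .profile_breakdown("preoperative", profile),
                 thresholds)
}

#' Score the perioperative risk-factor profile
#'
#' Sums the ten intraoperative factor points into the Perioperative
#' Adhesion Risk Score (3-31; the minimum of 3 reflects that every
#' operation has a duration and a type/site) and classifies it as low
#' (3-17), medium (18-28) or high (29-31) risk.
#'
#' @inheritParams score_preoperative
#' @param profile A [perioperative_profile()] (or a named list coercible
#'   to one).
#' @return An object of class `ars_score` (see [score_preoperative()]).
#' @examples
#' score_perioperative(perioperative_profile(
#'   duration_minutes = 100, surgery_type_site = "laparoscopy_other"))
#' @export
score_perioperative <- function(profile, thresholds = NULL) {
  if (!inherits(profile, "perioperative_profile")) {
    profile <- .profile_from_raw("perioperative", as.list(profile))
  }
  .new_ars_score("perioperative",
                 .profile_breakdown("perioperative", profile), thresholds)
}

#' Total Adhesion Risk Score
#'
#' Adds the two sub-scores of one patient into the total ARS. The total is
#' descriptive only: no combined low/medium/high thresholds are defined,
#' so the result deliberately carries no risk category — risk is always
#' read off the individual sub-scores.
#'
#' @param pre An `ars_score` with `sub_score = "preoperative"`.
#' @param peri An `ars_score` with `sub_score = "perioperative"`.
#' @return A single integer in 3-67.
#' @examples
#' pre <- score_preoperative(preoperative_profile())
#' peri <- score_perioperative(perioperative_profile(
#'   duration_minutes = 60, surgery_type_site = "laparoscopy_fallopian_tube"))
#' total_ars(pre, peri)  # 0 + 3 = 3
#' @export
total_ars <- function(pre, peri) {
  if (!inherits(pre, "ars_score") || !inherits(peri, "ars_score")) {
    stop("`pre` and `peri` must be ars_score objects", call. = FALSE)
  }
  if (pre$sub_score != "preoperative" || peri$sub_score != "perioperative") {
    stop(
      "total_ars() needs one preoperative and one perioperative score, got ",
      pre$sub_score, " + ", peri$sub_score,
      call. = FALSE
    )
  }
  pre$score + peri$score
}

#' @export
print.ars_score <- function(x, ...) {
  label <- if (x$sub_score == "preoperative") {
    "Preoperative Adhesion Risk Score"
  } else {
    "Perioperative Adhesion Risk Score"
  }
  cat(sprintf("%s: %d (%s risk)\n", label, x$score, x$risk_category))
  nz <- x$breakdown[x$breakdown > 0L]
  if (length(nz)) {
    cat("Contributing factors:\n")
    for (f in names(nz)) cat(sprintf("  %-38s %d\n", f, nz[[f]]))
  } else {
    cat("No contributing factors.\n")
  }
  invisible(x)
}

# Vectorised per-factor point matrix for a typed cohort data frame.
# `present` marks the rows that carry this profile; other rows get NA.
.points_matrix <- function(df, kind, present = rep(TRUE, nrow(df))) {
  fields <- .kind_fields(kind)
  m <- matrix(NA_integer_, nrow = nrow(df), ncol = length(fields),
              dimnames = list(NULL, fields))
  if (any(present)) {
    for (f in fields) {
      m[present, f] <- .factor_points(kind, f, df[[f]][present])
    }
  }
  m
}

# records -> wide typed data frame + presence flags
.records_to_df <- function(records) {
  n <- length(records)
  ids <- vapply(records, function(r) r$patient_id, character(1L))
  has_pre <- vapply(records, function(r) !is.null(r$preoperative),
                    logical(1L))
  has_peri <- vapply(records, function(r) !is.null(r$perioperative),
                     logical(1L))
  df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  get_col <- function(kind, f, has, na) {
    out <- rep(na, n)
    for (i in which(has)) out[i] <- records[[i]][[kind]][[f]]
    out
  }
  for (f in .preop_fields) {
    na <- if (f == "previous_surgery_count") NA_integer_ else
      if (f %in% names(.ars_enum_points)) NA_character_ else NA
    df[[f]] <- get_col("preoperative", f, has_pre, na)
  }
  for (f in .periop_fields) {
    na <- if (f == "duration_minutes") NA_real_ else
      if (f %in% names(.ars_enum_points)) NA_character_ else NA
    df[[f]] <- get_col("perioperative", f, has_peri, na)
  }
  list(df = df, has_pre = has_pre, has_peri = has_peri, ids = ids)
}

# wide (possibly partial) data frame -> presence flags; synthesises ids
.df_presence <- function(df) {
  n <- nrow(df)
  ids <- if ("patient_id" %in% names(df)) as.character(df$patient_id) else
    as.character(seq_len(n))
  presence <- function(fields) {
    cols <- intersect(fields, names(df))
    if (!length(cols)) return(rep(FALSE, n))
    Reduce(`|`, lapply(cols, function(c) !is.na(df[[c]])))
  }
  list(ids = ids, has_pre = presence(.preop_fields),
       has_peri = presence(.periop_fields))
}

#' Score a cohort of patients
#'
#' Computes both sub-scores, risk categories, the total ARS and the full
#' per-factor point breakdown for every record of a cohort. Accepts the
#' cohort object returned by [read_cohort()] or [generate_cohort()], a
#' plain list of [cohort_record()]s, or a wide data frame with one column
#' per factor (the column dictionary of [read_cohort()]).
#'
#' @param x Cohort input (see Details above).
#' @param sub_score `"both"` (default), `"preoperative"` or
#'   `"perioperative"`: which sub-scores to compute. The total ARS is
#'   reported only when both are computed.
#' @param thresholds Optional custom threshold table (see
#'   [ars_thresholds()]).
#' @param validate For data-frame input: validate every row before scoring
#'   (default). Set to `FALSE` only for data frames whose values are
#'   already typed and known to be valid — for example the output of
#'   [enumerate_profiles()] — where re-validation would dominate runtime.
#' @return A data frame with one row per patient and stable column order:
#'   `patient_id`, `preoperative_score`, `preoperative_risk`,
#'   `perioperative_score`, `perioperative_risk`, `total_ars`, then the
#'   per-factor point columns `pre_pts_*` and `peri_pts_*`. Sub-scores of
#'   absent profiles are `NA`.
#' @examples
#' coh <- generate_cohort(5, seed = 1)
#' score_cohort(coh)[, 1:6]
#' @export
score_cohort <- function(x, sub_score = c("both", "preoperative",
                                          "perioperative"),
                         thresholds = NULL, validate = TRUE) {
  sub_score <- match.arg(sub_score)
  if (inherits(x, "ars_cohort")) x <- x$records
  if (is.data.frame(x)) {
    if (validate) {
      parsed <- .df_to_records(x)
      if (nrow(parsed$issues)) {
        head_issues <- utils::head(parsed$issues, 10L)
        stop(
          "cohort contains invalid rows:\n",
          paste(sprintf("  row %s (%s): %s", head_issues$row,
                        head_issues$patient_id, head_issues$reason),
                collapse = "\n"),
          if (nrow(parsed$issues) > 10L) "\n  ...",
          call. = FALSE
        )
      }
      conv <- .records_to_df(parsed$records)
    } else {
      pres <- .df_presence(x)
      conv <- list(df = x, has_pre = pres$has_pre,
                   has_peri = pres$has_peri, ids = pres$ids)
    }
  } else if (is.list(x)) {
    if (!all(vapply(x, inherits, logical(1L), "cohort_record"))) {
      stop("`x` must be a cohort object, a list of cohort_record objects, ",
           "or a data frame", call. = FALSE)
    }
    conv <- .records_to_df(x)
  } else {
    stop("`x` must be a cohort object, a list of cohort_record objects, ",
         "or a data frame", call. = FALSE)
  }

  df <- conv$df
  n <- nrow(df)
  do_pre <- sub_score %in% c("both", "preoperative")
  do_peri <- sub_score %in% c("both", "perioperative")
  out <- data.frame(patient_id = conv$ids, stringsAsFactors = FALSE)

  pre_m <- peri_m <- NULL
  if (do_pre) {
    pre_m <- .points_matrix(df, "preoperative", conv$has_pre)
    sc <- rep(NA_integer_, n)
    sc[conv$has_pre] <- as.integer(rowSums(pre_m[conv$has_pre, , drop = FALSE]))
    rk <- rep(NA_character_, n)
    if (any(conv$has_pre)) {
      rk[conv$has_pre] <- classify(sc[conv$has_pre], "preoperative",
                                   thresholds)
    }
    out$preoperative_score <- sc
    out$preoperative_risk <- rk
  }
  if (do_peri) {
    peri_m <- .points_matrix(df, "perioperative", conv$has_peri)
    sc <- rep(NA_integer_, n)
    sc[conv$has_peri] <- as.integer(rowSums(peri_m[conv$has_peri, , drop = FALSE]))
    rk <- rep(NA_character_, n)
    if (any(conv$has_peri)) {
      rk[conv$has_peri] <- classify(sc[conv$has_peri], "perioperative",
                                    thresholds)
    }
    out$perioperative_score <- sc
    out$perioperative_risk <- rk
  }
  if (do_pre && do_peri) {
    out$total_ars <- out$preoperative_score + out$perioperative_score
  }
  if (do_pre) {
    for (f in .preop_fields) out[[paste0("pre_pts_", f)]] <- pre_m[, f]
  }
  if (do_peri) {
    for (f in .periop_fields) out[[paste0("peri_pts_", f)]] <- peri_m[, f]
  }
  out
}
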