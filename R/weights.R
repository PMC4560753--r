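# Factor dictionaries and consensus weight tables for the Adhesion Risk Score.
#
# The score is a weighted additive index: each of 20 risk factors (10
# preoperative, 10 perioperative) contributes an integer number of points in
# 0..4, and the sub-score is the plain sum. The point values below are the
# consensus weights; they are data, not tunables.

# Canonical field order. Breakdowns, file columns and enumerations all use
# this order, so output is byte-stable.
.preop_fields <- c(
  "previous_surgery_count",
  "history_postsurgical_adhesions",
  "concomitant_inflammation_or_infection",
  "endometriosis",
  "cancer",
  "radiation",
  "keloid_scarring",
  "prior_intraperitoneal_bleeding",
  "prior_postoperative_complications",
  "prior_postoperative_infection"
)

.periop_fields <- c(
  "adhesion_quality",
  "adhesion_severity",
  "bleeding_over_500ml",
  "duration_minutes",
  "complex_or_multiquadrant",
  "excessive_coagulation",
  "surgery_type_site",
  "foreign_body_placement",
  "electrical_scalpel",
  "peritoneal_closing"
)

# Preoperative sequelae of previous operations: only meaningful when at least
# one previous abdominal/pelvic surgery exists.
.preop_sequelae <- c(
  "prior_intraperitoneal_bleeding",
  "prior_postoperative_complications",
  "prior_postoperative_infection"
)

# Ordinal/categorical factors: level -> points. The first level of each
# vector is the "factor absent" level used as default for optional fields.
.ars_enum_points <- list(
  endometriosis = c(
    absent = 0L, minimal = 1L, mild = 2L, moderate = 3L, severe = 4L
  ),
  cancer = c(
    absent = 0L, gynaecologic = 2L, peritoneal_carcinomatosis = 2L,
    local_non_gynaecological = 3L, metastatic_extrapelvic = 2L
  ),
  radiation = c(absent = 0L, local = 4L, distant = 1L),
  adhesion_quality = c(none = 0L, filmy = 2L, vascular = 3L, dense = 4L),
  adhesion_severity = c(
    none = 0L, single = 1L, two_or_three = 2L, more_than_three = 3L,
    bowel_involvement = 4L
  ),
  surgery_type_site = c(
    laparoscopy_fallopian_tube = 1L, open_uterus = 3L,
    open_fallopian_tube = 2L, laparoscopy_adhesiolysis_uterus = 3L,
    laparoscopy_other = 2L, open_ovary = 4L
  )
)

# Binary factors: points awarded when present (0 when absent).
.ars_binary_points <- list(
  preoperative = c(
    history_postsurgical_adhesions = 4L,
    concomitant_inflammation_or_infection = 4L,
    keloid_scarring = 3L,
    prior_intraperitoneal_bleeding = 2L,
    prior_postoperative_complications = 4L,
    prior_postoperative_infection = 4L
  ),
  perioperative = c(
    bleeding_over_500ml = 4L,
    complex_or_multiquadrant = 3L,
    excessive_coagulation = 2L,
    foreign_body_placement = 3L,
    electrical_scalpel = 2L,
    peritoneal_closing = 1L
  )
)

# Enum factors that may legitimately be reported with several applicable
# levels in source data (e.g. two concurrent cancers); the maximum-weight
# level is scored, with a warning.
.multi_level_ok <- c(
  "cancer", "radiation", "surgery_type_site", "adhesion_severity"
)

# Accept "intraoperative" (and short forms) as an alias for the perioperative
# sub-score: both names are in clinical use.
.match_kind <- function(kind) {
  map <- c(
    preoperative = "preoperative", pre = "preoperative",
    perioperative = "perioperative", peri = "perioperative",
    intraoperative = "perioperative"
  )
  if (length(kind) != 1L || is.na(kind) || !kind %in% names(map)) {
    stop(
      "`sub_score` must be \"preoperative\" or \"perioperative\" ",
      "(alias: \"intraoperative\")",
      call. = FALSE
    )
  }
  unname(map[[kind]])
}

.kind_fields <- function(kind) {
  if (kind == "preoperative") .preop_fields else .periop_fields
}

.enum_weight <- function(factor, level) {
  pts <- .ars_enum_points[[factor]]
  level <- as.character(level)
  bad <- is.na(level) | !(level %in% names(pts))
  if (any(bad)) {
    stop(
      sprintf(
        "invalid %s level: %s (expected one of: %s)",
        factor, paste(sQuote(unique(level[bad])), collapse = ", "),
        paste(names(pts), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  unname(pts[level])
}

#' Points for the number of previous abdominal/pelvic surgeries
#'
#' The preoperative score awards 0 points for no previous abdominal or
#' pelvic surgery, 3 points for exactly one, and 4 points for more than one.
#'
#' @param count Non-negative whole number of previous abdominal/pelvic
#'   surgeries. Vectorised.
#' @return Integer points in `0:4`, one per element of `count`.
#' @examples
#' weight_previous_surgery(c(0, 1, 2, 5))
#' @export
weight_previous_surgery <- function(count) {
  if (length(count) == 0L || !is.numeric(count) || anyNA(count)) {
    stop("`count` must be numeric and non-missing", call. = FALSE)
  }
  if (any(count < 0) || any(count != trunc(count))) {
    stop(
      "previous_surgery_count must be a non-negative whole number",
      call. = FALSE
    )
  }
  as.integer(ifelse(count == 0, 0L, ifelse(count == 1, 3L, 4L)))
}

#' Points for endometriosis stage
#'
#' Endometriosis severity follows the rASRM classification: stage I
#' (minimal) through stage IV (severe) score 1 through 4 points; absence
#' scores 0.
#'
#' @param stage One of `"absent"`, `"minimal"`, `"mild"`, `"moderate"`,
#'   `"severe"`. Vectorised.
#' @return Integer points in `0:4`.
#' @examples
#' weight_endometriosis(c("absent", "mild", "severe"))
#' @export
weight_endometriosis <- function(stage) {
  .enum_weight("endometriosis", stage)
}

#' Points for cancer category
#'
#' Gynaecologic cancer, peritoneal carcinomatosis and metastatic cancer of
#' extrapelvic origin each score 2 points; local non-gynaecological cancer
#' scores 3. Exactly one category is scored per patient; when source data
#' marks several applicable categories the highest-weight one is used (see
#' [preoperative_profile()]).
#'
#' @param category One of `"absent"`, `"gynaecologic"`,
#'   `"peritoneal_carcinomatosis"`, `"local_non_gynaecological"`,
#'   `"metastatic_extrapelvic"`. Vectorised.
#' @return Integer points in `0:3`.
#' @export
weight_cancer <- function(category) {
  .enum_weight("cancer", category)
}

#' Points for radiation therapy in intra-abdominal cancer
#'
#' Local radiation therapy scores 4 points, radiation of distant sites 1,
#' no radiation 0.
#'
#' @param kind One of `"absent"`, `"local"`, `"distant"`. Vectorised.
#' @return Integer points in `0:4`.
#' @export
weight_radiation <- function(kind) {
  .enum_weight("radiation", kind)
}

#' Points for procedure duration
#'
#' Procedure duration is banded: under 90 minutes scores 2 points, 90
#' minutes up to and including 2 hours scores 3, and over 2 hours scores 4.
#' Band edges are sharp, which is why durations are accepted only as
#' minutes, never as free-text such as "1h30".
#'
#' @param duration_minutes Positive procedure duration in minutes.
#'   Vectorised.
#' @return Integer points in `2:4`.
#' @examples
#' weight_duration(c(60, 90, 120, 121))
#' @export
weight_duration <- function(duration_minutes) {
  if (length(duration_minutes) == 0L || !is.numeric(duration_minutes) ||
      anyNA(duration_minutes)) {
    stop("`duration_minutes` must be numeric and non-missing", call. = FALSE)
  }
  if (any(duration_minutes <= 0) || any(!is.finite(duration_minutes))) {
    stop("duration_minutes must be a positive number of minutes",
         call. = FALSE)
  }
  as.integer(
    ifelse(duration_minutes < 90, 2L,
           ifelse(duration_minutes <= 120, 3L, 4L))
  )
}

#' Points for the quality of pre-existing adhesions
#'
#' Filmy adhesions score 2 points, vascular 3, dense 4; no adhesions score
#' 0. (There is deliberately no 1-point grade for this factor.)
#'
#' @param quality One of `"none"`, `"filmy"`, `"vascular"`, `"dense"`.
#'   Vectorised.
#' @return Integer points in `0:4`.
#' @export
weight_adhesion_quality <- function(quality) {
  .enum_weight("adhesion_quality", quality)
}

#' Points for the severity (extent) of pre-existing adhesions
#'
#' Severity uses the classical four-grade extent classification (Knightly):
#' a single adhesion scores 1 point, two or three adhesions 2, more than
#' three 3, and adhesion(s) with bowel involvement 4; no adhesions score 0.
#'
#' @param severity One of `"none"`, `"single"`, `"two_or_three"`,
#'   `"more_than_three"`, `"bowel_involvement"`. Vectorised.
#' @return Integer points in `0:4`.
#' @export
weight_adhesion_severity <- function(severity) {
  .enum_weight("adhesion_severity", severity)
}

#' Points for the type and anatomical site of surgery
#'
#' Scores by approach and site: laparoscopy of the fallopian tube 1 point;
#' open fallopian-tube surgery and all other laparoscopic procedures 2;
#' open uterine surgery and laparoscopic adhesiolysis or uterine surgery 3;
#' open ovarian surgery 4.
#'
#' @param choice One of `"laparoscopy_fallopian_tube"`, `"open_uterus"`,
#'   `"open_fallopian_tube"`, `"laparoscopy_adhesiolysis_uterus"`,
#'   `"laparoscopy_other"`, `"open_ovary"`. Vectorised.
#' @return Integer points in `1:4`.
#' @export
weight_surgery_type_site <- function(choice) {
  .enum_weight("surgery_type_site", choice)
}

# points for one factor; `v` is an already-validated typed value (vectorised)
.factor_points <- function(kind, field, v) {
  switch(field,
    previous_surgery_count = weight_previous_surgery(v),
    endometriosis = weight_endometriosis(v),
    cancer = weight_cancer(v),
    radiation = weight_radiation(v),
    duration_minutes = weight_duration(v),
    adhesion_quality = weight_adhesion_quality(v),
    adhesion_severity = weight_adhesion_severity(v),
    surgery_type_site = weight_surgery_type_site(v),
    {
      w <- .ars_binary_points[[kind]][[field]]
      if (is.null(w)) stop("unknown factor: ", field, call. = FALSE)
      if (!is.logical(v) || anyNA(v)) {
        stop(field, " must be TRUE/FALSE and non-missing", call. = FALSE)
      }
      as.integer(v) * w
    }
  )
}

#' Consensus weight table for one sub-score
#'
#' Returns the full factor/level/points table behind one of the two
#' sub-scores, in canonical factor order. Useful for display (for example
#' as an operating-room aide-memoire) and for auditing the scoring engine.
#'
#' @param sub_score `"preoperative"` or `"perioperative"`
#'   (`"intraoperative"` is accepted as an alias).
#' @return A data frame with columns `factor`, `level`, `points`. Binary
#'   factors are listed with levels `absent`/`present`; previous surgeries
#'   and procedure duration with their band labels.
#' @examples
#' ars_weights("perioperative")
#' @export
ars_weights <- function(sub_score = c("preoperative", "perioperative")) {
  kind <- .match_kind(sub_score[[1L]])
  rows <- lapply(.kind_fields(kind), function(f) {
    if (f == "previous_surgery_count") {
      data.frame(
        factor = f, level = c("0", "1", ">1"),
        points = c(0L, 3L, 4L), stringsAsFactors = FALSE
      )
    } else if (f == "duration_minutes") {
      data.frame(
        factor = f, level = c("<90 min", "90 min-2 h", ">2 h"),
        points = c(2L, 3L, 4L), stringsAsFactors = FALSE
      )
    } else if (f %in% names(.ars_enum_points)) {
      pts <- .ars_enum_points[[f]]
      data.frame(
        factor = f, level = names(pts), points = unname(pts),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        factor = f, level = c("absent", "present"),
        points = c(0L, .ars_binary_points[[kind]][[f]]),
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
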