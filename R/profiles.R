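# Patient profiles: typed containers for the 10 preoperative and 10
# perioperative risk-factor values, with full validation of levels and
# cross-field rules.
#
# Two validation surfaces share one normaliser per profile:
#   * constructors (preoperative_profile / perioperative_profile) stop on
#     the first problem — programmatic use;
#   * validate_record() reports all problems without raising — batch use.

# Coerce a single raw value to logical. Accepts logical, 0/1 and the
# case-insensitive tokens true/false, yes/no, 1/0. Returns TRUE/FALSE,
# NA for missing/blank, or the string "invalid".
.coerce_bool <- function(v) {
  if (is.null(v) || length(v) == 0L) return(NA)
  if (length(v) != 1L) return("invalid")
  if (is.logical(v)) return(v[[1L]])
  if (is.numeric(v)) {
    if (is.na(v)) return(NA)
    if (v %in% c(0, 1)) return(v == 1)
    return("invalid")
  }
  if (is.character(v)) {
    s <- tolower(trimws(v))
    if (is.na(v) || !nzchar(s)) return(NA)
    if (s %in% c("true", "yes", "1")) return(TRUE)
    if (s %in% c("false", "no", "0")) return(FALSE)
  }
  "invalid"
}

# Coerce a single raw value to numeric; NA for missing, "invalid" otherwise.
.coerce_num <- function(v) {
  if (is.null(v) || length(v) == 0L) return(NA_real_)
  if (length(v) != 1L) return("invalid")
  if (is.numeric(v)) return(as.numeric(v))
  if (is.character(v)) {
    s <- trimws(v)
    if (is.na(v) || !nzchar(s)) return(NA_real_)
    x <- suppressWarnings(as.numeric(s))
    if (is.na(x)) return("invalid")
    return(x)
  }
  "invalid"
}

# Enum value: returns a length-1 character level, NA for missing, or a list
# of candidate levels when several were supplied (resolved by the caller
# under the maximum-weight rule for factors where that is allowed).
.coerce_enum <- function(v) {
  if (is.null(v) || length(v) == 0L) return(NA_character_)
  v <- as.character(unlist(v, use.names = FALSE))
  v <- v[!is.na(v) & nzchar(trimws(v))]
  if (length(v) == 0L) return(NA_character_)
  trimws(v)
}

.enum_issue <- function(field, value) {
  sprintf(
    "%s: unknown level %s (expected one of: %s)",
    field, paste(sQuote(value), collapse = ", "),
    paste(names(.ars_enum_points[[field]]), collapse = ", ")
  )
}

# Resolve a (possibly multi-valued) enum to one level. Multi-valued input is
# allowed only for factors where exactly one category is scored per patient
# (cancer, radiation, surgery type/site, adhesion severity): the
# highest-weight level wins, with a warning.
.resolve_enum <- function(field, value, issues, warnings) {
  levels <- names(.ars_enum_points[[field]])
  bad <- setdiff(value, levels)
  if (length(bad)) {
    issues <- c(issues, .enum_issue(field, bad))
    return(list(value = NA_character_, issues = issues, warnings = warnings))
  }
  if (length(value) > 1L) {
    if (!field %in% .multi_level_ok) {
      issues <- c(issues, sprintf("%s: expected a single level", field))
      return(list(value = NA_character_, issues = issues, warnings = warnings))
    }
    pts <- .ars_enum_points[[field]][value]
    keep <- value[[which.max(pts)]]
    warnings <- c(warnings, sprintf(
      "%s: multiple applicable levels (%s); scoring the highest-weight level '%s'",
      field, paste(value, collapse = ", "), keep
    ))
    value <- keep
  }
  list(value = value, issues = issues, warnings = warnings)
}

# Normalise a raw named list into fully-typed preoperative fields.
# Returns list(fields, issues, defaulted, warnings).
.normalize_preoperative <- function(x) {
  issues <- character()
  warnings <- character()
  defaulted <- character()
  unknown <- setdiff(names(x), .preop_fields)
  if (length(unknown)) {
    issues <- c(issues,
                paste0("unknown preoperative field: ",
                       paste(unknown, collapse = ", ")))
  }
  f <- list()

  v <- .coerce_num(x[["previous_surgery_count"]])
  if (identical(v, "invalid")) {
    issues <- c(issues, "previous_surgery_count: not a number")
  } else if (is.na(v)) {
    f$previous_surgery_count <- 0L
    defaulted <- c(defaulted, "previous_surgery_count")
  } else if (v < 0 || v != trunc(v)) {
    issues <- c(issues,
                "previous_surgery_count: must be a non-negative whole number")
  } else {
    f$previous_surgery_count <- as.integer(v)
  }

  for (fld in names(.ars_binary_points$preoperative)) {
    b <- .coerce_bool(x[[fld]])
    if (identical(b, "invalid")) {
      issues <- c(issues, paste0(
        fld, ": not a recognised boolean (use true/false, yes/no, 1/0)"))
    } else if (is.na(b)) {
      f[[fld]] <- FALSE
      defaulted <- c(defaulted, fld)
    } else {
      f[[fld]] <- b
    }
  }

  for (fld in c("endometriosis", "cancer", "radiation")) {
    v <- .coerce_enum(x[[fld]])
    if (length(v) == 1L && is.na(v)) {
      f[[fld]] <- "absent"
      defaulted <- c(defaulted, fld)
    } else {
      r <- .resolve_enum(fld, v, issues, warnings)
      issues <- r$issues
      warnings <- r$warnings
      if (!is.na(r$value)) f[[fld]] <- r$value
    }
  }

  # sequelae of previous operations require at least one previous operation
  if (!is.null(f$previous_surgery_count) && f$previous_surgery_count == 0L) {
    on_seq <- .preop_sequelae[vapply(.preop_sequelae,
                                     function(s) isTRUE(f[[s]]), logical(1L))]
    if (length(on_seq)) {
      issues <- c(issues, sprintf(
        paste0("%s: sequelae of previous operations apply only to patients ",
               "with at least one previous operation ",
               "(previous_surgery_count is 0)"),
        paste(on_seq, collapse = ", ")
      ))
    }
  }

  list(fields = f, issues = issues, defaulted = defaulted,
       warnings = warnings)
}

# Normalise a raw named list into fully-typed perioperative fields.
.normalize_perioperative <- function(x) {
  issues <- character()
  warnings <- character()
  defaulted <- character()
  unknown <- setdiff(names(x), .periop_fields)
  if (length(unknown)) {
    issues <- c(issues,
                paste0("unknown perioperative field: ",
                       paste(unknown, collapse = ", ")))
  }
  f <- list()

  # mandatory: every operation has a duration and a type/site
  v <- .coerce_num(x[["duration_minutes"]])
  if (identical(v, "invalid")) {
    issues <- c(issues,
                "duration_minutes: not a number (minutes expected)")
  } else if (is.na(v)) {
    issues <- c(issues, "duration_minutes: mandatory field is missing")
  } else if (!is.finite(v) || v <= 0) {
    issues <- c(issues, "duration_minutes: must be a positive number of minutes")
  } else {
    f$duration_minutes <- v
  }

  for (fld in c("adhesion_quality", "adhesion_severity",
                "surgery_type_site")) {
    v <- .coerce_enum(x[[fld]])
    if (length(v) == 1L && is.na(v)) {
      if (fld == "surgery_type_site") {
        issues <- c(issues, "surgery_type_site: mandatory field is missing")
      } else {
        f[[fld]] <- "none"
        defaulted <- c(defaulted, fld)
      }
    } else {
      r <- .resolve_enum(fld, v, issues, warnings)
      issues <- r$issues
      warnings <- r$warnings
      if (!is.na(r$value)) f[[fld]] <- r$value
    }
  }

  for (fld in names(.ars_binary_points$perioperative)) {
    b <- .coerce_bool(x[[fld]])
    if (identical(b, "invalid")) {
      issues <- c(issues, paste0(
        fld, ": not a recognised boolean (use true/false, yes/no, 1/0)"))
    } else if (is.na(b)) {
      f[[fld]] <- FALSE
      defaulted <- c(defaulted, fld)
    } else {
      f[[fld]] <- b
    }
  }

  # no adhesions means both quality and severity report none
  q <- f$adhesion_quality
  s <- f$adhesion_severity
  if (!is.null(q) && !is.null(s)) {
    if (q == "none" && s != "none") {
      issues <- c(issues, sprintf(
        "adhesion_severity: '%s' is inconsistent with adhesion_quality = 'none' (no adhesions means both report none)",
        s))
    } else if (q != "none" && s == "none") {
      issues <- c(issues, sprintf(
        "adhesion_severity: 'none' is inconsistent with adhesion_quality = '%s' (existing adhesions must have a severity grade)",
        q))
    }
  }

  list(fields = f, issues = issues, defaulted = defaulted,
       warnings = warnings)
}

.normalize_profile <- function(kind, x) {
  if (kind == "preoperative") .normalize_preoperative(x)
  else .normalize_perioperative(x)
}

.new_profile <- function(kind, fields) {
  structure(fields[.kind_fields(kind)],
            class = c(paste0(kind, "_profile"), "ars_profile"))
}

.profile_from_raw <- function(kind, x, what = paste(kind, "profile")) {
  n <- .normalize_profile(kind, x)
  for (w in n$warnings) warning(w, call. = FALSE)
  if (length(n$issues)) {
    stop("invalid ", what, ":\n  - ",
         paste(n$issues, collapse = "\n  - "), call. = FALSE)
  }
  .new_profile(kind, n$fields)
}

#' Preoperative risk-factor profile for one patient
#'
#' Bundles the ten preoperative risk factors, validated against the factor
#' dictionary. The three sequelae of previous operations (intraperitoneal
#' bleeding with an unexpected haemoglobin drop of at least 2 g%,
#' postoperative complications such as fistulas or abscesses, and
#' postoperative infection with fever of at least 38 degrees C for at least
#' two days) may only be `TRUE` when `previous_surgery_count >= 1`.
#'
#' If several applicable levels are supplied for `cancer` or `radiation`
#' (for example two concurrent malignancies), the highest-weight level is
#' scored and a warning is emitted: exactly one category per factor counts
#' towards the score.
#'
#' @param previous_surgery_count Number of previous abdominal/pelvic
#'   surgeries (non-negative whole number).
#' @param history_postsurgical_adhesions Known history of post-surgical
#'   adhesions.
#' @param concomitant_inflammation_or_infection Concomitant abdominal or
#'   gynaecological inflammation and/or infection.
#' @param endometriosis rASRM stage: `"absent"`, `"minimal"`, `"mild"`,
#'   `"moderate"`, `"severe"`.
#' @param cancer `"absent"`, `"gynaecologic"`,
#'   `"peritoneal_carcinomatosis"`, `"local_non_gynaecological"`,
#'   `"metastatic_extrapelvic"`.
#' @param radiation Radiation therapy in intra-abdominal cancer:
#'   `"absent"`, `"local"`, `"distant"`.
#' @param keloid_scarring Keloid scarring tendency.
#' @param prior_intraperitoneal_bleeding Unexpected haemoglobin drop of
#'   \eqn{\ge 2} g% after a previous operation.
#' @param prior_postoperative_complications Complications (fistulas,
#'   abscesses, ...) after a previous operation.
#' @param prior_postoperative_infection Postoperative infection
#'   (\eqn{\ge 38}{>= 38} degrees C for \eqn{\ge 2} days) after a previous
#'   operation.
#' @return An object of class `preoperative_profile`.
#' @examples
#' preoperative_profile()  # all factors absent: scores 0
#' preoperative_profile(previous_surgery_count = 2, endometriosis = "severe")
#' @export
preoperative_profile <- function(previous_surgery_count = 0L,
                                 history_postsurgical_adhesions = FALSE,
                                 concomitant_inflammation_or_infection = FALSE,
                                 endometriosis = "absent",
                                 cancer = "absent",
                                 radiation = "absent",
                                 keloid_scarring = FALSE,
                                 prior_intraperitoneal_bleeding = FALSE,
                                 prior_postoperative_complications = FALSE,
                                 prior_postoperative_infection = FALSE) {
  x <- list(
    previous_surgery_count = previous_surgery_count,
    history_postsurgical_adhesions = history_postsurgical_adhesions,
    concomitant_inflammation_or_infection = concomitant_inflammation_or_infection,
    endometriosis = endometriosis,
    cancer = cancer,
    radiation = radiation,
    keloid_scarring = keloid_scarring,
    prior_intraperitoneal_bleeding = prior_intraperitoneal_bleeding,
    prior_postoperative_complications = prior_postoperative_complications,
    prior_postoperative_infection = prior_postoperative_infection
  )
  .profile_from_raw("preoperative", x, "preoperative profile")
}

#' Perioperative (intraoperative) risk-factor profile for one patient
#'
#' Bundles the ten intraoperative risk factors. `duration_minutes` and
#' `surgery_type_site` are mandatory — every operation has a duration and
#' a type/site, which is why the perioperative sub-score can never be below
#' 3 points. All other factors default to absent. The adhesion fields are
#' linked: `adhesion_quality = "none"` if and only if
#' `adhesion_severity = "none"`.
#'
#' If several applicable levels are supplied for `surgery_type_site` or
#' `adhesion_severity` (for example an adhesion count category together
#' with bowel involvement), the highest-weight level is scored with a
#' warning.
#'
#' @param adhesion_quality Quality of pre-existing adhesions: `"none"`,
#'   `"filmy"`, `"vascular"`, `"dense"`.
#' @param adhesion_severity Extent of pre-existing adhesions: `"none"`,
#'   `"single"`, `"two_or_three"`, `"more_than_three"`,
#'   `"bowel_involvement"`.
#' @param bleeding_over_500ml Intraoperative bleeding over 500 ml.
#' @param duration_minutes Procedure duration in minutes (positive;
#'   mandatory).
#' @param complex_or_multiquadrant Complex or extensive surgery (for
#'   example enterotomy, oncological surgery, multi-quadrant
#'   adhesiolysis).
#' @param excessive_coagulation Coagulated area over 2 cm squared.
#' @param surgery_type_site Type and site of surgery (mandatory):
#'   `"laparoscopy_fallopian_tube"`, `"open_uterus"`,
#'   `"open_fallopian_tube"`, `"laparoscopy_adhesiolysis_uterus"`,
#'   `"laparoscopy_other"`, `"open_ovary"`.
#' @param foreign_body_placement Intra-abdominal placement of foreign
#'   bodies (for example meshes).
#' @param electrical_scalpel Use of an electrical scalpel.
#' @param peritoneal_closing Closure of the peritoneum.
#' @return An object of class `perioperative_profile`.
#' @examples
#' # the minimal possible operation: scores 3
#' perioperative_profile(duration_minutes = 60,
#'                       surgery_type_site = "laparoscopy_fallopian_tube")
#' @export
perioperative_profile <- function(adhesion_quality = "none",
                                  adhesion_severity = "none",
                                  bleeding_over_500ml = FALSE,
                                  duration_minutes,
                                  complex_or_multiquadrant = FALSE,
                                  excessive_coagulation = FALSE,
                                  surgery_type_site,
                                  foreign_body_placement = FALSE,
                                  electrical_scalpel = FALSE,
                                  peritoneal_closing = FALSE) {
  x <- list(
    adhesion_quality = adhesion_quality,
    adhesion_severity = adhesion_severity,
    bleeding_over_500ml = bleeding_over_500ml,
    duration_minutes = if (missing(duration_minutes)) NULL else duration_minutes,
    complex_or_multiquadrant = complex_or_multiquadrant,
    excessive_coagulation = excessive_coagulation,
    surgery_type_site = if (missing(surgery_type_site)) NULL else surgery_type_site,
    foreign_body_placement = foreign_body_placement,
    electrical_scalpel = electrical_scalpel,
    peritoneal_closing = peritoneal_closing
  )
  .profile_from_raw("perioperative", x, "perioperative profile")
}

#' One patient record in a cohort
#'
#' A cohort record couples an opaque patient identifier with one or both
#' risk-factor profiles. At least one profile must be present.
#'
#' @param patient_id Non-empty identifier string, unique within a cohort.
#' @param preoperative A [preoperative_profile()], a named list coercible
#'   to one, or `NULL`.
#' @param perioperative A [perioperative_profile()], a named list coercible
#'   to one, or `NULL`.
#' @return An object of class `cohort_record`.
#' @export
cohort_record <- function(patient_id, preoperative = NULL,
                          perioperative = NULL) {
  if (length(patient_id) != 1L || is.na(patient_id) ||
      !nzchar(trimws(as.character(patient_id)))) {
    stop("`patient_id` must be a single non-empty string", call. = FALSE)
  }
  if (is.null(preoperative) && is.null(perioperative)) {
    stop("a cohort record needs at least one profile", call. = FALSE)
  }
  if (!is.null(preoperative) &&
      !inherits(preoperative, "preoperative_profile")) {
    preoperative <- .profile_from_raw("preoperative",
                                      as.list(preoperative))
  }
  if (!is.null(perioperative) &&
      !inherits(perioperative, "perioperative_profile")) {
    perioperative <- .profile_from_raw("perioperative",
                                       as.list(perioperative))
  }
  structure(
    list(patient_id = as.character(patient_id),
         preoperative = preoperative, perioperative = perioperative),
    class = "cohort_record"
  )
}

.empty_report <- function() {
  data.frame(profile = character(), field = character(),
             reason = character(), stringsAsFactors = FALSE)
}

.report_from_issues <- function(kind, issues) {
  if (!length(issues)) return(.empty_report())
  field <- sub(":.*$", "", issues)
  field[!grepl(":", issues, fixed = TRUE)] <- NA_character_
  data.frame(profile = kind, field = field, reason = issues,
             stringsAsFactors = FALSE)
}

#' Validate a cohort record without raising
#'
#' Checks every factor value and the cross-field rules (adhesion quality
#' and severity must agree on the presence of adhesions; sequelae of
#' previous operations require at least one previous operation) and
#' returns a report rather than an error. An empty report means the record
#' is valid.
#'
#' @param record A [cohort_record()], or a list with elements
#'   `patient_id` and raw `preoperative`/`perioperative` named lists (as
#'   read from a structured-record file).
#' @return A data frame with columns `profile`, `field`, `reason`; zero
#'   rows if and only if the record is valid.
#' @examples
#' rec <- cohort_record("P1", preoperative = preoperative_profile())
#' validate_record(rec)  # empty: the record is valid
#' @export
validate_record <- function(record) {
  rep <- .empty_report()
  pid <- record$patient_id
  if (is.null(pid) || length(pid) != 1L || is.na(pid) ||
      !nzchar(trimws(as.character(pid)))) {
    rep <- rbind(rep, data.frame(
      profile = "record", field = "patient_id",
      reason = "patient_id: must be a non-empty string",
      stringsAsFactors = FALSE))
  }
  if (is.null(record$preoperative) && is.null(record$perioperative)) {
    rep <- rbind(rep, data.frame(
      profile = "record", field = NA_character_,
      reason = "record: at least one profile must be present",
      stringsAsFactors = FALSE))
  }
  for (kind in c("preoperative", "perioperative")) {
    p <- record[[kind]]
    if (is.null(p)) next
    n <- .normalize_profile(kind, as.list(p))
    rep <- rbind(rep, .report_from_issues(kind, n$issues))
  }
  rownames(rep) <- NULL
  rep
}

#' @export
print.ars_profile <- function(x, ...) {
  kind <- if (inherits(x, "preoperative_profile")) "Preoperative"
          else "Perioperative"
  cat(kind, "adhesion risk profile\n")
  for (f in names(x)) {
    cat(sprintf("  %-38s %s\n", f, format(x[[f]])))
  }
  invisible(x)
}
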