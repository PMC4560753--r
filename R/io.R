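# Cohort file I/O: delimited (CSV, one patient per row, canonical
# snake-case column dictionary) and structured records (JSON, one object
# per patient with nested preoperative/perioperative objects).
#
# Parsing is total: a readable file never crashes the reader — every row
# either becomes a validated record or a structured row-level report.
# Unreadable files, unknown columns and duplicate patient identifiers are
# hard errors in every mode.

.cohort_columns <- function() c("patient_id", .preop_fields, .periop_fields)

.new_ars_cohort <- function(records, issues, n_input) {
  structure(list(records = records, issues = issues, n_input = n_input),
            class = "ars_cohort")
}

.issue_df <- function(row = integer(), patient_id = character(),
                      profile = character(), field = character(),
                      reason = character()) {
  data.frame(row = row, patient_id = patient_id, profile = profile,
             field = field, reason = reason, stringsAsFactors = FALSE)
}

# Wide data frame (raw or typed) -> records + row-level issue reports.
# Emits one aggregated warning when optional fields were defaulted.
.df_to_records <- function(df) {
  unknown <- setdiff(names(df), .cohort_columns())
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  ids <- if ("patient_id" %in% names(df)) as.character(df$patient_id) else
    as.character(seq_len(n))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate patient_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  pre_cols <- intersect(.preop_fields, names(df))
  peri_cols <- intersect(.periop_fields, names(df))

  records <- vector("list", n)
  keep <- logical(n)
  issues <- list()
  defaulted <- character()

  for (i in seq_len(n)) {
    pid <- ids[i]
    if (is.na(pid) || !nzchar(trimws(pid))) {
      issues[[length(issues) + 1L]] <- .issue_df(
        i, NA_character_, "record", "patient_id",
        "patient_id: must be a non-empty string")
      next
    }
    row_raw <- function(cols) {
      x <- lapply(cols, function(c) df[[c]][[i]])
      names(x) <- cols
      x
    }
    pre_raw <- row_raw(pre_cols)
    peri_raw <- row_raw(peri_cols)
    has_val <- function(x) {
      any(vapply(x, function(v) length(v) > 0L && !all(is.na(v)),
                 logical(1L)))
    }
    has_pre <- length(pre_cols) > 0L && has_val(pre_raw)
    has_peri <- length(peri_cols) > 0L && has_val(peri_raw)
    if (!has_pre && !has_peri) {
      issues[[length(issues) + 1L]] <- .issue_df(
        i, pid, "record", NA_character_,
        "record: no risk-factor data in either profile")
      next
    }
    row_issues <- .empty_report()
    profs <- list(preoperative = NULL, perioperative = NULL)
    for (kind in c("preoperative", "perioperative")) {
      present <- if (kind == "preoperative") has_pre else has_peri
      if (!present) next
      raw <- if (kind == "preoperative") pre_raw else peri_raw
      nn <- .normalize_profile(kind, raw)
      defaulted <- c(defaulted, nn$defaulted)
      for (w in nn$warnings) warning("row ", i, " (", pid, "): ", w,
                                     call. = FALSE)
      if (length(nn$issues)) {
        row_issues <- rbind(row_issues,
                            .report_from_issues(kind, nn$issues))
      } else {
        profs[[kind]] <- .new_profile(kind, nn$fields)
      }
    }
    if (nrow(row_issues)) {
      issues[[length(issues) + 1L]] <- .issue_df(
        rep(i, nrow(row_issues)), rep(pid, nrow(row_issues)),
        row_issues$profile, row_issues$field, row_issues$reason)
    } else {
      records[[i]] <- structure(
        list(patient_id = pid, preoperative = profs$preoperative,
             perioperative = profs$perioperative),
        class = "cohort_record")
      keep[i] <- TRUE
    }
  }

  if (length(defaulted)) {
    tab <- table(defaulted)
    warning(
      "missing optional fields defaulted to absent/false: ",
      paste(sprintf("%s (%d row%s)", names(tab), as.integer(tab),
                    ifelse(tab > 1L, "s", "")), collapse = ", "),
      call. = FALSE
    )
  }
  issues <- if (length(issues)) do.call(rbind, issues) else .issue_df()
  rownames(issues) <- NULL
  list(records = records[keep], issues = issues, n_input = n)
}

# structured-record list (parsed JSON) -> records + issues
.list_to_records <- function(lst) {
  if (!is.list(lst)) {
    stop("structured-record input must be an array of patient objects",
         call. = FALSE)
  }
  n <- length(lst)
  ids <- vapply(lst, function(r) {
    p <- r[["patient_id"]]
    if (is.null(p) || length(p) != 1L) NA_character_ else as.character(p)
  }, character(1L))
  dup <- unique(ids[!is.na(ids)][duplicated(ids[!is.na(ids)])])
  if (length(dup)) {
    stop("duplicate patient_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  records <- vector("list", n)
  keep <- logical(n)
  issues <- list()
  defaulted <- character()
  for (i in seq_len(n)) {
    r <- lst[[i]]
    pid <- ids[i]
    if (is.na(pid) || !nzchar(trimws(pid))) {
      issues[[length(issues) + 1L]] <- .issue_df(
        i, NA_character_, "record", "patient_id",
        "patient_id: must be a non-empty string")
      next
    }
    if (is.null(r$preoperative) && is.null(r$perioperative)) {
      issues[[length(issues) + 1L]] <- .issue_df(
        i, pid, "record", NA_character_,
        "record: at least one profile must be present")
      next
    }
    row_issues <- .empty_report()
    profs <- list(preoperative = NULL, perioperative = NULL)
    for (kind in c("preoperative", "perioperative")) {
      if (is.null(r[[kind]])) next
      nn <- .normalize_profile(kind, as.list(r[[kind]]))
      defaulted <- c(defaulted, nn$defaulted)
      for (w in nn$warnings) warning("record ", i, " (", pid, "): ", w,
                                     call. = FALSE)
      if (length(nn$issues)) {
        row_issues <- rbind(row_issues, .report_from_issues(kind, nn$issues))
      } else {
        profs[[kind]] <- .new_profile(kind, nn$fields)
      }
    }
    if (nrow(row_issues)) {
      issues[[length(issues) + 1L]] <- .issue_df(
        rep(i, nrow(row_issues)), rep(pid, nrow(row_issues)),
        row_issues$profile, row_issues$field, row_issues$reason)
    } else {
      records[[i]] <- structure(
        list(patient_id = pid, preoperative = profs$preoperative,
             perioperative = profs$perioperative),
        class = "cohort_record")
      keep[i] <- TRUE
    }
  }
  if (length(defaulted)) {
    tab <- table(defaulted)
    warning(
      "missing optional fields defaulted to absent/false: ",
      paste(sprintf("%s (%d record%s)", names(tab), as.integer(tab),
                    ifelse(tab > 1L, "s", "")), collapse = ", "),
      call. = FALSE
    )
  }
  issues <- if (length(issues)) do.call(rbind, issues) else .issue_df()
  rownames(issues) <- NULL
  list(records = records[keep], issues = issues, n_input = n)
}

#' Read a patient cohort from a file
#'
#' Reads, validates and types a cohort of per-patient risk-factor records.
#' Two formats are supported. `"delimited"` is UTF-8 comma-separated text
#' with a header row and one patient per row; columns are `patient_id`
#' plus any subset of the 20 canonical factor columns (see
#' [ars_weights()] for names and levels). `"structured_records"` is a JSON
#' array of objects with `patient_id` and nested
#' `preoperative`/`perioperative` objects mirroring the profile fields.
#'
#' Booleans accept `true/false`, `yes/no`, `1/0` case-insensitively; enum
#' fields accept exactly the canonical level token (no fuzzy matching, to
#' keep clinical semantics unambiguous); procedure duration is accepted in
#' minutes only. Missing optional fields default to absent/false with an
#' aggregated warning; missing mandatory fields (`duration_minutes`,
#' `surgery_type_site`) invalidate the row. Invalid rows never crash the
#' reader: they are returned as structured reports with row number, field
#' and reason.
#'
#' @param path Path to the input file.
#' @param format `"delimited"` (CSV) or `"structured_records"` (JSON).
#' @param strict If `TRUE`, any invalid row is escalated to an error.
#' @return An object of class `ars_cohort`: a list with `records` (valid
#'   [cohort_record()]s), `issues` (data frame with columns `row`,
#'   `patient_id`, `profile`, `field`, `reason`) and `n_input` (rows
#'   read).
#' @export
read_cohort <- function(path, format = c("delimited", "structured_records"),
                        strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- if (format == "delimited") {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE,
                          na.strings = c("NA", ""),
                          fileEncoding = "UTF-8")
    .df_to_records(df)
  } else {
    .list_to_records(jsonlite::fromJSON(path, simplifyVector = FALSE))
  }
  if (strict && nrow(parsed$issues)) {
    head_issues <- utils::head(parsed$issues, 10L)
    stop(
      "invalid rows in strict mode:\n",
      paste(sprintf("  row %s (%s): %s", head_issues$row,
                    head_issues$patient_id, head_issues$reason),
            collapse = "\n"),
      if (nrow(parsed$issues) > 10L) "\n  ...",
      call. = FALSE
    )
  }
  .new_ars_cohort(parsed$records, parsed$issues, parsed$n_input)
}

#' @export
print.ars_cohort <- function(x, ...) {
  cat(sprintf("Adhesion risk cohort: %d valid record(s) of %d read",
              length(x$records), x$n_input))
  n_pre <- sum(vapply(x$records, function(r) !is.null(r$preoperative),
                      logical(1L)))
  n_peri <- sum(vapply(x$records, function(r) !is.null(r$perioperative),
                       logical(1L)))
  cat(sprintf(" (%d preoperative, %d perioperative profile(s))\n",
              n_pre, n_peri))
  if (nrow(x$issues)) {
    cat(sprintf("%d validation issue(s); first few:\n",
                nrow(x$issues)))
    print(utils::head(x$issues, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' Write a cohort's risk-factor data to a file
#'
#' Writes the factor values (not scores) of a cohort in either supported
#' format, using the canonical column dictionary, so that
#' [read_cohort()] round-trips the cohort.
#'
#' @param cohort An `ars_cohort` or list of [cohort_record()]s.
#' @param path Output path.
#' @param format `"delimited"` or `"structured_records"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort,
                         path,
                         format = c("delimited", "structured_records")) {
  format <- match.arg(format)
  records <- if (inherits(cohort, "ars_cohort")) cohort$records else cohort
  if (format == "delimited") {
    conv <- .records_to_df(records)
    utils::write.csv(conv$df, path, row.names = FALSE, na = "")
  } else {
    lst <- lapply(records, function(r) {
      out <- list(patient_id = r$patient_id)
      if (!is.null(r$preoperative)) {
        out$preoperative <- unclass(r$preoperative)
      }
      if (!is.null(r$perioperative)) {
        out$perioperative <- unclass(r$perioperative)
      }
      out
    })
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write scored results to a file
#'
#' Writes the output of [score_cohort()] — identifiers, sub-scores, risk
#' categories, total ARS and the full per-factor point breakdown — in a
#' stable column order. [read_results()] round-trips the file exactly.
#'
#' @param scored A scored data frame from [score_cohort()].
#' @param path Output path.
#' @param format `"delimited"` (CSV) or `"structured_records"` (JSON).
#' @return `path`, invisibly.
#' @export
write_results <- function(scored, path,
                          format = c("delimited", "structured_records")) {
  format <- match.arg(format)
  if (!is.data.frame(scored) || !"patient_id" %in% names(scored)) {
    stop("`scored` must be a data frame from score_cohort()",
         call. = FALSE)
  }
  if (format == "delimited") {
    utils::write.csv(scored, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(scored, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

# column-wise type restoration so write/read round-trips exactly
.retype_results <- function(df) {
  for (nm in names(df)) {
    if (nm == "patient_id") {
      df[[nm]] <- as.character(df[[nm]])
    } else if (grepl("_risk$", nm)) {
      df[[nm]] <- as.character(df[[nm]])
    } else {
      df[[nm]] <- as.integer(df[[nm]])
    }
  }
  df
}

#' Read scored results back from a file
#'
#' Inverse of [write_results()]: restores the scored data frame with its
#' original column types (`patient_id` and risk categories as character,
#' scores and point breakdowns as integer).
#'
#' @param path Path written by [write_results()].
#' @param format `"delimited"` or `"structured_records"`.
#' @return The scored data frame.
#' @export
read_results <- function(path,
                         format = c("delimited", "structured_records")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (format == "delimited") {
    utils::read.csv(path, check.names = FALSE, na.strings = c("NA", ""),
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  .retype_results(df)
}
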