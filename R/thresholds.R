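# Risk stratification thresholds.
#
# The published cutoffs started from tertiles of the achievable ranges and
# were then adjusted after field testing; the perioperative intervals are
# therefore not arithmetic tertiles. The printed intervals are authoritative
# and inclusive at both ends.

.ars_ranges <- list(
  preoperative = c(0L, 36L),
  perioperative = c(3L, 31L)
)

.default_thresholds <- data.frame(
  sub_score = rep(c("preoperative", "perioperative"), each = 3L),
  risk = rep(c("low", "medium", "high"), 2L),
  lower = c(0L, 13L, 25L, 3L, 18L, 29L),
  upper = c(12L, 24L, 36L, 17L, 28L, 31L),
  stringsAsFactors = FALSE
)

#' Risk thresholds for the two sub-scores
#'
#' Default stratification: preoperative 0-12 low, 13-24 medium, 25-36 high;
#' perioperative 3-17 low, 18-28 medium, 29-31 high. All interval endpoints
#' are inclusive and the intervals partition the achievable range of each
#' sub-score.
#'
#' @return A data frame with columns `sub_score`, `risk`, `lower`, `upper`
#'   (six rows, both sub-scores).
#' @examples
#' ars_thresholds()
#' @export
ars_thresholds <- function() .default_thresholds

# A custom threshold table must still partition the achievable ranges:
# ordered low/medium/high with inclusive integer bounds, no gaps/overlaps.
.validate_thresholds <- function(th) {
  need <- c("sub_score", "risk", "lower", "upper")
  if (!is.data.frame(th) || !all(need %in% names(th))) {
    stop("thresholds must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (kind in c("preoperative", "perioperative")) {
    sub <- th[th$sub_score == kind, , drop = FALSE]
    if (nrow(sub) != 3L || !identical(sub$risk, c("low", "medium", "high"))) {
      stop("thresholds for ", kind,
           " must have rows low, medium, high in order", call. = FALSE)
    }
    rng <- .ars_ranges[[kind]]
    lo <- as.integer(sub$lower)
    hi <- as.integer(sub$upper)
    if (anyNA(lo) || anyNA(hi) || any(lo > hi)) {
      stop("threshold bounds for ", kind, " must be integers with lower <= upper",
           call. = FALSE)
    }
    if (lo[1L] != rng[1L] || hi[3L] != rng[2L] ||
        lo[2L] != hi[1L] + 1L || lo[3L] != hi[2L] + 1L) {
      stop("thresholds for ", kind, " must partition ", rng[1L], "-", rng[2L],
           " with no gaps or overlaps", call. = FALSE)
    }
  }
  invisible(th)
}

#' Classify a sub-score as low, medium or high adhesion risk
#'
#' Maps an achieved sub-score to its risk category using inclusive interval
#' thresholds. A score outside the achievable range of the sub-score
#' (preoperative 0-36, perioperative 3-31) signals a scoring bug upstream
#' and raises an error rather than being clamped.
#'
#' @param score Integer sub-score(s).
#' @param sub_score `"preoperative"` or `"perioperative"` (alias
#'   `"intraoperative"`).
#' @param thresholds Optional custom threshold table in the format of
#'   [ars_thresholds()] (for sensitivity exploration); it must still
#'   partition the achievable range.
#' @return Character vector of `"low"`, `"medium"`, `"high"`.
#' @examples
#' classify(c(12, 13, 25), "preoperative")
#' classify(29, "perioperative")
#' @export
classify <- function(score, sub_score, thresholds = NULL) {
  kind <- .match_kind(sub_score)
  th <- if (is.null(thresholds)) .default_thresholds else {
    .validate_thresholds(thresholds)
    thresholds
  }
  if (length(score) == 0L || !is.numeric(score) || anyNA(score) ||
      any(score != trunc(score))) {
    stop("`score` must be a non-missing integer sub-score", call. = FALSE)
  }
  rng <- .ars_ranges[[kind]]
  if (any(score < rng[1L] | score > rng[2L])) {
    bad <- unique(score[score < rng[1L] | score > rng[2L]])
    stop(
      sprintf(
        "score %s is outside the achievable %s range [%d, %d]",
        paste(bad, collapse = ", "), kind, rng[1L], rng[2L]
      ),
      call. = FALSE
    )
  }
  sub <- th[th$sub_score == kind, , drop = FALSE]
  idx <- findInterval(score, sub$lower)
  sub$risk[idx]
}

#' Read an optional configuration file
#'
#' Reads a YAML configuration recognising the keys `strict` (logical,
#' batch-reading strictness), `format` (`"delimited"` or
#' `"structured_records"`) and `thresholds` (custom risk intervals for
#' sensitivity exploration, as
#' `thresholds: {preoperative: {low: [0, 12], medium: [13, 24], high:
#' [25, 36]}, ...}`). Defaults reproduce the published score exactly; the
#' configuration only overrides what it names.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `strict`, `format`, `thresholds` (the
#'   latter a validated threshold data frame, or `NULL` to use the
#'   defaults).
#' @export
read_ars_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(strict = FALSE, format = NULL, thresholds = NULL)
  if (!is.null(cfg$strict)) out$strict <- isTRUE(cfg$strict)
  if (!is.null(cfg$format)) {
    out$format <- match.arg(cfg$format, c("delimited", "structured_records"))
  }
  if (!is.null(cfg$thresholds)) {
    th <- .default_thresholds
    for (kind in names(cfg$thresholds)) {
      k <- .match_kind(kind)
      for (risk in names(cfg$thresholds[[kind]])) {
        b <- cfg$thresholds[[kind]][[risk]]
        if (length(b) != 2L) {
          stop("threshold ", kind, "/", risk,
               " must be a [lower, upper] pair", call. = FALSE)
        }
        i <- th$sub_score == k & th$risk == risk
        if (!any(i)) stop("unknown risk category: ", risk, call. = FALSE)
        th$lower[i] <- as.integer(b[[1L]])
        th$upper[i] <- as.integer(b[[2L]])
      }
    }
    .validate_thresholds(th)
    out$thresholds <- th
  }
  out
}
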