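# Cohort-level reporting: risk-category distribution, score histogram and
# mean per-factor contribution for a scored cohort.

# one-decimal percentages that sum exactly to 100: the rounding residue is
# assigned to the largest category
.round_pct <- function(p) {
  r <- round(p, 1L)
  resid <- round(100 - sum(r), 1L)
  if (length(r) && resid != 0) {
    i <- which.max(p)
    r[i] <- round(r[i] + resid, 1L)
  }
  r
}

.summarize_kind <- function(scored, kind) {
  score_col <- paste0(kind, "_score")
  risk_col <- paste0(kind, "_risk")
  if (!score_col %in% names(scored)) return(NULL)
  present <- !is.na(scored[[score_col]])
  if (!any(present)) return(NULL)
  scores <- scored[[score_col]][present]
  risks <- factor(scored[[risk_col]][present],
                  levels = c("low", "medium", "high"))
  counts <- as.integer(table(risks))
  categories <- data.frame(
    risk = c("low", "medium", "high"),
    count = counts,
    percent = .round_pct(100 * counts / length(scores)),
    stringsAsFactors = FALSE
  )
  rng <- .ars_ranges[[kind]]
  bins <- rng[1L]:rng[2L]
  histogram <- data.frame(
    score = bins,
    count = vapply(bins, function(b) sum(scores == b), integer(1L))
  )
  pts_cols <- paste0(if (kind == "preoperative") "pre_pts_" else "peri_pts_",
                     .kind_fields(kind))
  pts_cols <- intersect(pts_cols, names(scored))
  factors <- data.frame(
    factor = sub("^(pre|peri)_pts_", "", pts_cols),
    mean_points = vapply(pts_cols,
                         function(cn) mean(scored[[cn]][present]),
                         numeric(1L)),
    stringsAsFactors = FALSE
  )
  factors <- factors[order(-factors$mean_points, factors$factor), ]
  rownames(factors) <- NULL
  list(n = length(scores), categories = categories,
       histogram = histogram, top_factors = factors)
}

#' Summarise a scored cohort
#'
#' Condenses the output of [score_cohort()] into, per sub-score: the
#' count and percentage of patients in each risk category (percentages to
#' one decimal, summing exactly to 100), a score histogram over the full
#' achievable range (including zero-count bins), and the risk factors
#' ranked by mean contributed points. The summary is deterministic and
#' invariant under record order.
#'
#' @param scored A scored data frame from [score_cohort()].
#' @return An object of class `ars_cohort_summary`: a list with elements
#'   `n_patients`, `empty` (marker for an empty cohort), and per-sub-score
#'   lists (`preoperative`, `perioperative`) each holding `n`,
#'   `categories`, `histogram` and `top_factors`. Sub-scores with no
#'   scored patients are `NULL`.
#' @examples
#' summarize_cohort(score_cohort(generate_cohort(50, seed = 7)))
#' @export
summarize_cohort <- function(scored) {
  if (!is.data.frame(scored)) {
    stop("`scored` must be a data frame from score_cohort()", call. = FALSE)
  }
  if (nrow(scored) == 0L) {
    return(structure(
      list(n_patients = 0L, empty = TRUE,
           preoperative = NULL, perioperative = NULL),
      class = "ars_cohort_summary"
    ))
  }
  structure(
    list(
      n_patients = nrow(scored),
      empty = FALSE,
      preoperative = .summarize_kind(scored, "preoperative"),
      perioperative = .summarize_kind(scored, "perioperative")
    ),
    class = "ars_cohort_summary"
  )
}

#' @export
print.ars_cohort_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Adhesion risk cohort summary: empty cohort (no patients)\n")
    return(invisible(x))
  }
  cat(sprintf("Adhesion risk cohort summary (%d patient(s))\n",
              x$n_patients))
  for (kind in c("preoperative", "perioperative")) {
    s <- x[[kind]]
    if (is.null(s)) next
    label <- if (kind == "preoperative") "Preoperative" else "Perioperative"
    cat(sprintf("\n%s Adhesion Risk Score (n = %d)\n", label, s$n))
    for (i in seq_len(nrow(s$categories))) {
      cat(sprintf("  %-6s risk: %5d  (%5.1f%%)\n",
                  s$categories$risk[i], s$categories$count[i],
                  s$categories$percent[i]))
    }
    nz <- s$top_factors[s$top_factors$mean_points > 0, , drop = FALSE]
    if (nrow(nz)) {
      cat("  Top contributing factors (mean points):\n")
      for (i in seq_len(min(5L, nrow(nz)))) {
        cat(sprintf("    %-38s %.2f\n", nz$factor[i], nz$mean_points[i]))
      }
    }
  }
  invisible(x)
}

#' Write a cohort summary to delimited files
#'
#' Machine-readable companion to the printed summary: writes the
#' category-distribution table (and optionally the histograms) as CSV.
#'
#' @param summary An `ars_cohort_summary` from [summarize_cohort()].
#' @param path Output path for the category table.
#' @param histogram_path Optional output path for the score histograms.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, histogram_path = NULL) {
  if (!inherits(summary, "ars_cohort_summary")) {
    stop("`summary` must come from summarize_cohort()", call. = FALSE)
  }
  rows <- list()
  hrows <- list()
  for (kind in c("preoperative", "perioperative")) {
    s <- summary[[kind]]
    if (is.null(s)) next
    cat_df <- s$categories
    cat_df <- cbind(sub_score = kind, cat_df, stringsAsFactors = FALSE)
    rows[[kind]] <- cat_df
    h <- cbind(sub_score = kind, s$histogram, stringsAsFactors = FALSE)
    hrows[[kind]] <- h
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sub_score = character(), risk = character(),
               count = integer(), percent = numeric())
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(histogram_path)) {
    hout <- if (length(hrows)) do.call(rbind, hrows) else
      data.frame(sub_score = character(), score = integer(),
                 count = integer())
    rownames(hout) <- NULL
    utils::write.csv(hout, histogram_path, row.names = FALSE)
  }
  invisible(path)
}
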