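#' Welch t statistic from group summaries
#'
#' Computes `|mean1 - mean2| / sqrt(se1^2 + se2^2)` from published group
#' means and standard errors — the form in which between-group distance
#' comparisons are typically reported (e.g. distances of identified vs
#' unidentified nesting cliffs to the nearest imagery-covered road). If
#' sample sizes are supplied, Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value are returned as secondary outputs.
#'
#' @param mean1,mean2 group means.
#' @param se1,se2 group standard errors of the mean (> 0).
#' @param n1,n2 optional group sample sizes (for df and p).
#' @return List with `t` (unrounded), `t2` (rounded to 2 decimals) and,
#'   when `n1`/`n2` are given, `df` and `p`.
#' @export
welch_t_from_summaries <- function(mean1, se1, mean2, se2,
                                   n1 = NULL, n2 = NULL) {
  if (!is_number(se1) || !is_number(se2) || se1 <= 0 || se2 <= 0)
    stop_invalid("standard errors must be positive")
  t <- abs(mean1 - mean2) / sqrt(se1^2 + se2^2)
  out <- list(t = t, t2 = round(t, 2))
  if (!is.null(n1) && !is.null(n2)) {
    df <- (se1^2 + se2^2)^2 /
      (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
    out$df <- df
    out$p <- 2 * stats::pt(-t, df)
  }
  out
}

#' Detection rate
#'
#' Share of `n` items that were detected, as a percentage; returned both
#' exactly and rounded to the nearest integer (the precision detection
#' tables are printed at, e.g. 97 of 148 cliffs -> 66%).
#'
#' @param k number detected (0 <= k <= n).
#' @param n total number (> 0).
#' @return List with `pct` (exact) and `pct_int` (nearest integer).
#' @export
detection_rate <- function(k, n) {
  if (!is_number(k) || !is_number(n) || n <= 0 || k < 0 || k > n)
    stop_invalid("need 0 <= k <= n with n > 0")
  p <- 100 * k / n
  list(pct = p, pct_int = as.integer(round(p)))
}

#' Chi-square test for a 2x2 count table
#'
#' Pearson chi-square test of independence for the table
#' `rbind(c(a, b), c(c, d))`, with optional Yates continuity correction;
#' used e.g. to compare detection counts between species.
#'
#' @param a,b,c,d non-negative cell counts with positive margins.
#' @param yates apply the continuity correction.
#' @return List with `statistic`, `df` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, yates = FALSE) {
  tab <- matrix(c(a, c, b, d), 2)
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_invalid("counts must be >= 0 with positive row and column sums")
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Median and 75th percentile of distances
#'
#' Order-statistic summary of a distance sample (linear interpolation
#' between order statistics, [stats::quantile()] type 7 — the same
#' percentile rule used for slope thresholds).
#'
#' @param distances non-empty numeric vector (m).
#' @return List with `median` and `p75`.
#' @export
distance_summary <- function(distances) {
  if (!length(distances) || anyNA(distances))
    stop_invalid("non-empty distance sample required")
  q <- stats::quantile(distances, c(0.5, 0.75), type = 7, names = FALSE)
  list(median = q[1], p75 = q[2])
}

#' Remote feature-detection table
#'
#' For each fine-scale cliff feature recorded in the field (white excrement
#' spots, caves, vegetation), counts the cliffs bearing it, the subset also
#' seen remotely, and the remote detection percentage — the layout of a
#' feature-detection summary table.
#'
#' @param sites data frame of cliff sites with logical columns
#'   `has_white_spots`, `has_cave`, `has_vegetation`,
#'   `remote_white_spots`, `remote_cave`, `remote_vegetation` and
#'   `remote_identified`.
#' @return Data frame with columns `feature`, `field_n`, `remote_n`,
#'   `remote_pct` (exact), `remote_pct_int`; percentage is `NA` for
#'   features never recorded in the field.
#' @export
feature_detection_table <- function(sites) {
  feats <- c(white_spots = "white_spots", cave = "cave",
             vegetation = "vegetation")
  rows <- lapply(names(feats), function(f) {
    field <- sites[[paste0("has_", f)]]
    remote <- sites[[paste0("remote_", f)]]
    if (any(remote & !sites$remote_identified))
      stop_invalid("remote feature flags require remote_identified")
    field_n <- sum(field)
    remote_n <- sum(field & remote)
    if (field_n > 0) {
      dr <- detection_rate(remote_n, field_n)
      data.frame(feature = f, field_n = field_n, remote_n = remote_n,
                 remote_pct = dr$pct, remote_pct_int = dr$pct_int)
    } else {
      data.frame(feature = f, field_n = 0L, remote_n = 0L,
                 remote_pct = NA_real_, remote_pct_int = NA_integer_)
    }
  })
  do.call(rbind, rows)
}
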