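#' Slope sample at occupied nesting cliffs
#'
#' Reads the slope value at the cell containing each site, in order of site
#' id. These occupied-cliff slopes are the calibration sample from which
#' classification thresholds are drawn.
#'
#' @param slopes a slope [elev_grid()] from [terrain_slope()].
#' @param sites data frame of cliff sites with columns `id`, `x`, `y`.
#' @return Numeric vector of gradients, one per site, ordered by `id`.
#' @export
occupied_slope_sample <- function(slopes, sites) {
  sites <- sites[order(sites$id), , drop = FALSE]
  vals <- value_at(slopes, sites$x, sites$y)
  if (anyNA(vals))
    stop_invalid("site '%s' lies on nodata slope",
                 sites$id[which(is.na(vals))[1]])
  vals
}

#' Slope thresholds from an occupied-cliff sample
#'
#' The three thresholds used to map candidate cliffs: the minimum occupied
#' slope (`s_min`), and the 25th and 50th percentiles (`s_25`, `s_50`),
#' computed by linear interpolation between order statistics
#' ([stats::quantile()] type 7). In the source field study these were
#' 0.34, 0.63 and 0.68 for 148 vulture nesting cliffs.
#'
#' @param sample non-empty numeric vector of gradients.
#' @return Object of class `slope_thresholds`: list with `s_min`, `s_25`,
#'   `s_50` (`s_min <= s_25 <= s_50`).
#' @export
slope_thresholds <- function(sample) {
  if (!length(sample) || anyNA(sample))
    stop_invalid("threshold sample must be non-empty and free of NA")
  q <- stats::quantile(sample, c(0.25, 0.5), type = 7, names = FALSE)
  structure(list(s_min = min(sample), s_25 = q[1], s_50 = q[2]),
            class = "slope_thresholds")
}

#' @export
print.slope_thresholds <- function(x, ...) {
  cat(sprintf("slope thresholds: s_min = %.3f, s_25 = %.3f, s_50 = %.3f\n",
              x$s_min, x$s_25, x$s_50))
  invisible(x)
}

#' Threshold a slope grid into a candidate-cliff map
#'
#' A cell is a candidate cliff iff its slope is `>= threshold` (so the
#' minimum-slope occupied cliff is itself captured by the `s_min` map).
#' Nodata slope cells are mapped as non-cliff and flagged invalid.
#'
#' @param slopes a slope [elev_grid()].
#' @param threshold gradient threshold (>= 0).
#' @return An [elev_grid()] with values 1 (cliff) / 0 (non-cliff), plus an
#'   attribute `valid`: logical matrix, `FALSE` where slope was nodata.
#' @export
classify_cliffs <- function(slopes, threshold) {
  if (!is_number(threshold) || threshold < 0)
    stop_invalid("`threshold` must be a non-negative gradient")
  v <- slopes$values
  cliff <- ifelse(!is.na(v) & v >= threshold, 1, 0)
  out <- elev_grid(cliff, slopes$cell_size, slopes$xll, slopes$yll,
                   slopes$nodata)
  attr(out, "valid") <- !is.na(v)
  out
}
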