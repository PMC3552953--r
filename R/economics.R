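#' Survey cost parameters
#'
#' Constants of the on-ground survey-by-car model: driving speed and fuel
#' cost. The remote (street-level imagery) survey has zero monetary cost.
#' Defaults follow the field protocol this package models: 30 km/h mean
#' survey speed and 0.19 euro per km driven.
#'
#' @param ground_speed mean driving speed, km/h (> 0).
#' @param euro_per_km cost per km driven, euro (>= 0).
#' @return List of class `cost_params`.
#' @export
cost_params <- function(ground_speed = 30, euro_per_km = 0.19) {
  if (!is_number(ground_speed) || ground_speed <= 0)
    stop_invalid("`ground_speed` must be > 0 km/h")
  if (!is_number(euro_per_km) || euro_per_km < 0)
    stop_invalid("`euro_per_km` must be >= 0")
  structure(list(ground_speed = ground_speed, euro_per_km = euro_per_km),
            class = "cost_params")
}

#' On-ground survey time
#'
#' Time to drive a road set at the mean survey speed: `60 * road_km /
#' ground_speed` minutes.
#'
#' @param road_km drivable road length, km (>= 0); vectorized.
#' @param params a [cost_params()].
#' @return Minutes.
#' @export
ground_time <- function(road_km, params = cost_params()) {
  if (any(road_km < 0)) stop_invalid("`road_km` must be >= 0")
  60 * road_km / params$ground_speed
}

#' On-ground survey monetary cost
#'
#' @inheritParams ground_time
#' @return Euro (`road_km * euro_per_km`).
#' @export
ground_cost <- function(road_km, params = cost_params()) {
  if (any(road_km < 0)) stop_invalid("`road_km` must be >= 0")
  road_km * params$euro_per_km
}

#' Per-surveyed-area rate
#'
#' Normalizes a survey total (minutes or euro) by the viewshed area it
#' covered, giving the min/km2 or euro/km2 rates of a survey-effort table.
#'
#' @param total minutes or euro; vectorized.
#' @param viewshed_km2 surveyed (visible) area, km2 (> 0).
#' @return `total / viewshed_km2`.
#' @export
per_area_rate <- function(total, viewshed_km2) {
  if (any(viewshed_km2 <= 0))
    stop_invalid("rate undefined for zero surveyed area")
  total / viewshed_km2
}

#' Fraction of the ground viewshed covered remotely
#'
#' The share of the area surveyable on the ground that the remote-imagery
#' survey also covers; this coincident fraction drives the savings of a
#' combined survey.
#'
#' @param viewshed_remote,viewshed_ground areas, km2; vectorized.
#' @return Fraction in `[0, 1]`.
#' @export
coincident_fraction <- function(viewshed_remote, viewshed_ground) {
  if (any(viewshed_ground <= 0))
    stop_invalid("ground viewshed must be > 0")
  f <- viewshed_remote / viewshed_ground
  if (any(f > 1 + 1e-9))
    stop_invalid("remote viewshed exceeds ground viewshed")
  pmin(f, 1)
}

#' Savings of a combined remote + on-ground survey
#'
#' Models replacing the on-ground survey of the coincident area by the
#' (faster, money-free) remote survey. With coincident fraction `f`,
#' per-km2 time rates `t_g` (ground) and `t_r` (remote) and per-km2 money
#' rate `c_g`:
#' `time_saved = f * viewshed_ground * (t_g - t_r)`,
#' `cost_saved = f * viewshed_ground * c_g`,
#' `pct_time = 100 * time_saved / (viewshed_ground * t_g)` and
#' `pct_cost = 100 * f` (the remote survey costs no money).
#'
#' @param viewshed_ground,viewshed_remote areas, km2; vectorized.
#' @param t_g,t_r per-km2 time rates, min/km2.
#' @param c_g per-km2 monetary rate, euro/km2.
#' @return Data frame with columns `time_saved_min`, `cost_saved_euro`,
#'   `pct_time`, `pct_cost` and logical `remote_slower` (`TRUE` where
#'   `t_r > t_g`, i.e. the time saving is negative).
#' @export
combined_savings <- function(viewshed_ground, viewshed_remote,
                             t_g, t_r, c_g) {
  f <- coincident_fraction(viewshed_remote, viewshed_ground)
  time_saved <- f * viewshed_ground * (t_g - t_r)
  cost_saved <- f * viewshed_ground * c_g
  slower <- t_r > t_g
  if (any(slower))
    warning("remote survey slower than ground on some squares; ",
            "negative time saving reported")
  data.frame(time_saved_min = time_saved,
             cost_saved_euro = cost_saved,
             pct_time = 100 * time_saved / (viewshed_ground * t_g),
             pct_cost = 100 * f,
             remote_slower = slower)
}

#' Paired two-sample tests for per-square survey effort
#'
#' Thin wrappers around [stats::wilcox.test()] and [stats::t.test()] for
#' comparing paired per-square measurements (e.g. min/km2 under two survey
#' methods). `wilcoxon_signed_rank()` drops zero differences and uses the
#' exact signed-rank null for n <= 25 untied pairs; if every pair is tied
#' it returns `V = 0, p = 1` (total agreement carries no evidence of a
#' difference).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return `wilcoxon_signed_rank()`: list with `V` and `p`;
#'   `paired_t()`: list with `t`, `df` and `p`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_invalid("paired samples of equal length >= 2 required")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) return(list(V = 0, p = 1))
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = length(d) <= 25))
  list(V = unname(res$statistic), p = res$p.value)
}

#' @rdname wilcoxon_signed_rank
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_invalid("paired samples of equal length >= 2 required")
  if (stats::sd(x - y) == 0)
    stop_invalid("all paired differences equal: t undefined")
  res <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
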