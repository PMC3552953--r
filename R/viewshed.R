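#' Line of sight over terrain
#'
#' Tests whether the straight sightline from an observer (ground elevation
#' plus `eye_height`) to a target (ground elevation plus `target_height`)
#' clears the terrain. The terrain is evaluated exactly where the sightline
#' crosses the grid lines through cell centres — values interpolate
#' linearly between the two adjacent cell centres there (the classic "R3"
#' test) — and additionally at the midpoint of each interval between
#' crossings, where the bilinear surface is quadratic along the ray;
#' ground elevations at the endpoints are bilinear. A target in the
#' observer's own cell is always visible. Nodata terrain anywhere under the
#' sightline blocks it; nodata under either endpoint is an error.
#'
#' @param dem an [elev_grid()].
#' @param x0,y0 observer position (m).
#' @param x1,y1 target position (m).
#' @param eye_height observer height above ground (m, >= 0).
#' @param target_height target height above ground (m, >= 0).
#' @return `TRUE` if the target is visible.
#' @export
line_of_sight <- function(dem, x0, y0, x1, y1, eye_height = 2.5,
                          target_height = 0) {
  c0 <- point_to_cell(dem, x0, y0)
  c1 <- point_to_cell(dem, x1, y1)
  z0 <- elevation_at(dem, x0, y0)
  z1 <- elevation_at(dem, x1, y1)
  if (is.na(z0) || is.na(z1))
    stop_invalid("line of sight endpoint on nodata terrain")
  if (all(c0 == c1)) return(TRUE)
  e0 <- z0 + eye_height
  e1 <- z1 + target_height
  tt <- crossing_params(dem, x0, y0, x1, y1)
  # between crossings the bilinear surface is quadratic along the ray, so
  # the interval midpoints are checked as well as the crossings
  tt <- sort(c(tt, midpoints(tt)))
  terr <- elevation_at(dem, x0 + tt * (x1 - x0), y0 + tt * (y1 - y0))
  sight <- e0 + tt * (e1 - e0)
  if (anyNA(terr)) return(FALSE)
  all(terr <= sight + 1e-9)
}

# midpoints of the intervals that a sorted set of parameters cuts (0, 1)
# into, endpoints included
midpoints <- function(tt) {
  b <- c(0, tt, 1)
  (b[-1] + b[-length(b)]) / 2
}

# parameters t in (0,1) where the segment crosses cell-centre grid lines
crossing_params <- function(dem, x0, y0, x1, y1) {
  nr <- nrow(dem$values); nc <- ncol(dem$values); cs <- dem$cell_size
  dx <- x1 - x0; dy <- y1 - y0
  tt <- numeric(0)
  if (abs(dx) > 0) {
    xc <- dem$xll + (seq_len(nc) - 0.5) * cs
    xc <- xc[xc > min(x0, x1) & xc < max(x0, x1)]
    tt <- c(tt, (xc - x0) / dx)
  }
  if (abs(dy) > 0) {
    yc <- dem$yll + (nr - seq_len(nr) + 0.5) * cs
    yc <- yc[yc > min(y0, y1) & yc < max(y0, y1)]
    tt <- c(tt, (yc - y0) / dy)
  }
  eps <- 1e-12
  sort(tt[tt > eps & tt < 1 - eps])
}

#' Viewshed from a set of observers
#'
#' Marks each non-nodata cell visible if [line_of_sight()] succeeds from at
#' least one observer within `max_distance` to the cell centre. With zero
#' observers no cell is visible. Observers are tried nearest first, so the
#' common case (a cell seen from a nearby road) exits early.
#'
#' @param dem an [elev_grid()].
#' @param observers data frame with columns `x`, `y`, `eye_height`, e.g.
#'   from [observers_along_roads()].
#' @param max_distance maximum observer-to-cell distance (m), default
#'   unlimited.
#' @param target_height target height above ground (m).
#' @return An [elev_grid()] of the same geometry with values 1 (visible)
#'   or 0; nodata terrain cells are 0.
#' @export
viewshed <- function(dem, observers, max_distance = Inf, target_height = 0) {
  v <- dem$values
  out <- elev_grid(matrix(0, nrow(v), ncol(v)), dem$cell_size, dem$xll,
                   dem$yll, dem$nodata)
  if (!nrow(observers)) return(out)
  out$values <- .viewshed_cpp(v, dem$cell_size, dem$xll, dem$yll,
                              as.numeric(observers$x),
                              as.numeric(observers$y),
                              as.numeric(observers$eye_height),
                              max_distance, target_height)
  out
}

#' Visible percentage of a region
#'
#' @param vis a 0/1 visibility grid from [viewshed()].
#' @param region_mask an [elev_grid()] of the same geometry with 0/1 values
#'   (or a logical/numeric matrix) marking the region of interest; `NULL`
#'   means the whole grid.
#' @return Percentage (0-100) of in-region cells that are visible.
#' @export
visible_fraction <- function(vis, region_mask = NULL) {
  m <- if (is.null(region_mask)) {
    matrix(TRUE, nrow(vis$values), ncol(vis$values))
  } else if (inherits(region_mask, "elev_grid")) {
    if (!same_geometry(vis, region_mask))
      stop_invalid("region mask geometry differs from visibility grid")
    !is.na(region_mask$values) & region_mask$values != 0
  } else {
    region_mask != 0
  }
  n <- sum(m)
  if (n == 0) stop_invalid("empty region: visible fraction undefined")
  100 * sum(vis$values[m] != 0) / n
}
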