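#' Terrain slope by Horn's method
#'
#' Computes the slope surface of a DEM as a dimensionless gradient
#' (rise/run) using Horn's 3x3 weighted finite differences, the de facto
#' GIS standard. For a window
#' \preformatted{ a b c
#'  d e f
#'  g h i }
#' the gradient components are
#' `dz/dx = ((c + 2f + i) - (a + 2d + g)) / (8 cs)` and
#' `dz/dy = ((g + 2h + i) - (a + 2b + c)) / (8 cs)`, and the slope is
#' `sqrt((dz/dx)^2 + (dz/dy)^2)`. No padding is applied: edge cells, and
#' interior cells whose 3x3 window contains nodata, are nodata in the
#' result.
#'
#' @param dem an [elev_grid()] with at least 3 rows and 3 columns.
#' @return An [elev_grid()] of the same geometry holding gradients (>= 0).
#' @examples
#' dem <- elev_grid(outer(rep(1, 5), (1:5) * 5) * 0.5, cell_size = 5)
#' terrain_slope(dem)$values[3, 3]   # plane z = 0.5 x -> gradient 0.5
#' @export
terrain_slope <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L)
    stop_invalid("slope needs a grid of at least 3 x 3 cells")
  cs <- dem$cell_size
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  a <- z[ri - 1, ci - 1, drop = FALSE]; b <- z[ri - 1, ci, drop = FALSE]
  cc <- z[ri - 1, ci + 1, drop = FALSE]
  d <- z[ri, ci - 1, drop = FALSE];     f <- z[ri, ci + 1, drop = FALSE]
  g <- z[ri + 1, ci - 1, drop = FALSE]; h <- z[ri + 1, ci, drop = FALSE]
  i9 <- z[ri + 1, ci + 1, drop = FALSE]
  e <- z[ri, ci, drop = FALSE]
  dzdx <- ((cc + 2 * f + i9) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i9) - (a + 2 * b + cc)) / (8 * cs)
  out <- matrix(NA_real_, nr, nc)
  out[ri, ci] <- sqrt(dzdx^2 + dzdy^2)
  # the stencil does not touch the centre cell, but a window containing
  # nodata anywhere (centre included) must yield nodata
  out[ri, ci][is.na(e)] <- NA_real_
  elev_grid(out, cs, dem$xll, dem$yll, dem$nodata)
}
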