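# fixtures and independent oracles used across the suite

flat_dem <- function(n = 10, cs = 10, z = 100) {
  elev_grid(matrix(z, n, n), cell_size = cs)
}

# affine plane z = a x + b y + c sampled at cell centres
plane_dem <- function(a, b, c = 0, n = 9, cs = 5) {
  x <- (seq_len(n) - 0.5) * cs
  y <- (n - seq_len(n) + 0.5) * cs
  elev_grid(outer(y, x, function(yy, xx) a * xx + b * yy + c),
            cell_size = cs)
}

rugged_dem <- function(seed, n = 20, cs = 10, relief = 40) {
  set.seed(seed)
  x <- seq_len(n)
  z <- relief * outer(sin(x / runif(1, 2, 4) + runif(1, 0, 6)),
                      cos(x / runif(1, 2, 4) + runif(1, 0, 6)))
  # spatially correlated roughness: white noise smoothed with a 3x3 mean,
  # as real terrain is smooth at the cell scale
  e <- matrix(rnorm((n + 2)^2, 0, relief / 6), n + 2, n + 2)
  sm <- (e[1:n, 1:n] + e[1:n, 2:(n + 1)] + e[1:n, 3:(n + 2)] +
           e[2:(n + 1), 1:n] + e[2:(n + 1), 2:(n + 1)] +
           e[2:(n + 1), 3:(n + 2)] + e[3:(n + 2), 1:n] +
           e[3:(n + 2), 2:(n + 1)] + e[3:(n + 2), 3:(n + 2)]) / 9
  elev_grid(z + sm, cell_size = cs)
}

# dense-ray visibility oracle: bilinear terrain sampled every cell_size/10
dense_ray_visible <- function(dem, x0, y0, x1, y1, eye_height = 2.5,
                              target_height = 0) {
  c0 <- point_to_cell(dem, x0, y0)
  c1 <- point_to_cell(dem, x1, y1)
  if (all(c0 == c1)) return(TRUE)
  e0 <- elevation_at(dem, x0, y0) + eye_height
  e1 <- elevation_at(dem, x1, y1) + target_height
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  tt <- seq(0, 1, length.out = max(ceiling(len / (dem$cell_size / 10)), 2))
  tt <- tt[tt > 1e-12 & tt < 1 - 1e-12]
  terr <- elevation_at(dem, x0 + tt * (x1 - x0), y0 + tt * (y1 - y0))
  sight <- e0 + tt * (e1 - e0)
  all(terr <= sight + 1e-9)
}

# brute-force observer count for one polyline by walking its arc length
walk_observer_count <- function(m, spacing) {
  total <- sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
  at <- 0
  n <- 0
  while (at < total - 1e-9) {
    n <- n + 1
    at <- at + spacing
  }
  n + 1   # final endpoint always included
}

# confusion counts of the published accuracy table (methods as columns)
table2_counts <- list(
  sv    = confusion_2x2(tp = 50, fn = 0,  fp = 0, tn = 50),
  s_min = confusion_2x2(tp = 49, fn = 1,  fp = 5, tn = 45),
  s_25  = confusion_2x2(tp = 29, fn = 21, fp = 0, tn = 50),
  s_50  = confusion_2x2(tp = 22, fn = 28, fp = 0, tn = 50))

# tiny pipeline configuration for fast end-to-end tests
small_config <- function(seed = 1L) {
  cfg <- default_config(seed = seed)
  cfg$synth <- list(n_rows = 50, n_cols = 50, road_spacing = 1500,
                    scarp_count = 5, n_nest_sites = 60)
  cfg$viewshed$observer_spacing <- 400
  cfg
}
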