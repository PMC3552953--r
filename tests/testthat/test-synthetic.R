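test_that("landscapes are seeded, scarp-free when asked, and cliff-steep", {
  gentle <- synth_config(seed = 2, scarp_count = 0, base_amplitude = 20,
                         n_rows = 40, n_cols = 40)
  land <- make_landscape(gentle)
  expect_equal(sum(land$truth$values), 0)
  expect_lt(max(terrain_slope(land$dem)$values, na.rm = TRUE), 0.1)

  again <- make_landscape(gentle)
  expect_identical(land$dem$values, again$dem$values)

  full <- make_landscape(synth_config(seed = 2))
  expect_false(identical(full$dem$values,
                         make_landscape(synth_config(seed = 3))$dem$values))
})

test_that("a designed scarp face is recovered by the slope operator", {
  # 20 m of height over a 10 m face (5 cells of 2 m) -> gradient 2.0
  cfg <- synth_config(seed = 4, n_rows = 60, n_cols = 60, cell_size = 2,
                      base_amplitude = 0, scarp_count = 1,
                      scarp_height = 20, scarp_face_cells = 5,
                      scarp_backslope_cells = 25, road_spacing = 40)
  land <- make_landscape(cfg)
  slopes <- terrain_slope(land$dem)
  expect_gt(sum(land$truth$values), 0)
  face_slopes <- slopes$values[land$truth$values != 0]
  expect_equal(max(face_slopes, na.rm = TRUE), 2, tolerance = 1e-9)
})

test_that("imagery coverage hits the configured share of paved length", {
  for (sd in 1:4) {
    cfg <- synth_config(seed = sd)
    land <- make_landscape(cfg)
    roads <- make_roads(cfg, land$dem)
    share <- road_length(roads, covered_only = TRUE) /
      road_length(roads, surface = "paved")
    expect_equal(share, 0.49, tolerance = 0.02)
    expect_equal(road_length(roads, covered_only = TRUE,
                             surface = "unpaved"), 0)
  }
  cfg0 <- synth_config(seed = 1, coverage_fraction = 0)
  land0 <- make_landscape(cfg0)
  expect_equal(road_length(make_roads(cfg0, land0$dem), TRUE), 0)
  cfg1 <- synth_config(seed = 1, coverage_fraction = 1)
  r1 <- make_roads(cfg1, land0$dem)
  expect_equal(road_length(r1, covered_only = TRUE),
               road_length(r1, surface = "paved"))
})

test_that("nest sites sit on cliff cells with configured prevalences", {
  cfg <- synth_config(seed = 8, n_nest_sites = 1400)
  land <- make_landscape(cfg)
  sites <- make_nest_sites(land$truth, cfg)
  expect_equal(nrow(sites), 1400)
  expect_true(all(value_at(land$truth, sites$x, sites$y) == 1))
  expect_false(any(duplicated(sites[, c("x", "y")])))

  # observed prevalence within 3 binomial SEs of the configured value
  for (f in c("white_spots", "cave", "vegetation")) {
    p <- cfg[[paste0("prev_", f)]]
    obs <- mean(sites[[paste0("has_", f)]])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 1400))
  }
  # every nesting site is occupied by at least one species
  expect_true(all(sites$occupied_by_griffon | sites$occupied_by_egyptian))

  all_on <- make_nest_sites(land$truth,
                            synth_config(seed = 8, n_nest_sites = 50,
                                         prev_white_spots = 1))
  expect_true(all(all_on$has_white_spots))
  expect_error(make_nest_sites(land$truth,
                               synth_config(seed = 8, n_nest_sites = 1e5)),
               "cliff cells")
})

test_that("identification halves at d50 and never fires when invisible", {
  cfg <- synth_config(seed = 10)
  net <- road_network(list(cbind(x = c(0, 0), y = c(-1e4, 1e4))),
                      covered = TRUE)
  n <- 4000
  sites <- data.frame(id = seq_len(n), x = cfg$d50, y = seq_len(n),
                      has_white_spots = TRUE, has_cave = TRUE,
                      has_vegetation = TRUE,
                      remote_identified = FALSE,
                      remote_white_spots = FALSE, remote_cave = FALSE,
                      remote_vegetation = FALSE)
  out <- simulate_identification(sites, net, vis = NULL, cfg)
  expect_equal(out$dist_covered_road_m, rep(cfg$d50, n))
  expect_lt(abs(mean(out$remote_identified) - 0.5), 3 * sqrt(0.25 / n))

  dark <- elev_grid(matrix(0, 200, 200), cell_size = 100, yll = 0)
  out2 <- simulate_identification(sites, net, vis = dark, cfg)
  expect_false(any(out2$remote_identified))
  expect_false(any(out2$remote_white_spots))
})

test_that("identified sites lie nearer covered roads than unidentified", {
  cfg <- synth_config(seed = 12)
  net <- road_network(list(cbind(x = c(0, 0), y = c(0, 2000))),
                      covered = TRUE)
  n <- 2000
  set.seed(61)
  sites <- data.frame(id = seq_len(n), x = runif(n, 0, 3000),
                      y = runif(n, 0, 2000),
                      has_white_spots = FALSE, has_cave = FALSE,
                      has_vegetation = FALSE,
                      remote_identified = FALSE,
                      remote_white_spots = FALSE, remote_cave = FALSE,
                      remote_vegetation = FALSE)
  out <- simulate_identification(sites, net, vis = NULL, cfg)
  expect_gt(sum(out$remote_identified), 100)
  expect_lt(median(out$dist_covered_road_m[out$remote_identified]),
            median(out$dist_covered_road_m[!out$remote_identified]))
})

test_that("survey time rates match their configured moments", {
  squares <- data.frame(viewshed_ground_km2 = c(80, 90, 100),
                        viewshed_remote_km2 = c(40, 45, 50))
  exact <- simulate_survey_times(
    squares, synth_config(seed = 3, rate_ground_sd = 0,
                          rate_remote_sd = 0))
  expect_equal(exact$time_ground_min, 3.97 * squares$viewshed_ground_km2)
  expect_equal(exact$time_remote_min, 0.91 * squares$viewshed_remote_km2)

  big <- data.frame(viewshed_ground_km2 = rep(100, 1000),
                    viewshed_remote_km2 = rep(50, 1000))
  noisy <- simulate_survey_times(big, synth_config(seed = 5))
  expect_true(all(noisy$rate_ground > 0 & noisy$rate_remote > 0))
  expect_lt(abs(mean(noisy$rate_ground) - 3.97), 3 * 2.94 / sqrt(1000))
  expect_lt(abs(mean(noisy$rate_remote) - 0.91), 3 * 0.21 / sqrt(1000))
})

test_that("the logistic distance-decay parameters are recoverable by ML", {
  cfg <- synth_config(seed = 20)
  set.seed(71)
  d <- runif(1500, 0, 3000)
  p <- stats::plogis((cfg$d50 - d) / cfg$logistic_scale)
  id <- stats::runif(1500) < p
  fit <- fit_distance_decay(d, id)
  expect_lt(abs(fit$d50 - cfg$d50) / cfg$d50, 0.10)
  expect_lt(abs(fit$scale - cfg$logistic_scale) / cfg$logistic_scale, 0.25)
})
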