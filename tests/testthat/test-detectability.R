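test_that("nearest covered-road distance is a point-to-segment minimum", {
  net <- road_network(list(cbind(x = c(-5, 5), y = c(0, 0)),
                           cbind(x = c(100, 100), y = c(0, 50))),
                      covered = c(TRUE, FALSE))
  expect_equal(nearest_covered_road_distance(0, 10, net), 10)
  expect_equal(nearest_covered_road_distance(3, 0, net), 0)
  # beyond the segment end the distance is to the endpoint
  expect_equal(nearest_covered_road_distance(8, 4, net), 5)
  # the uncovered polyline is ignored even when nearer
  expect_equal(nearest_covered_road_distance(100, 25, net),
               sqrt(95^2 + 25^2))

  none <- road_network(list(cbind(x = c(0, 1), y = c(0, 0))))
  expect_error(nearest_covered_road_distance(0, 0, none), "covered")
})

test_that("segment distances agree with a dense vertex-sampling oracle", {
  set.seed(43)
  for (i in 1:8) {
    seg <- matrix(runif(4, -50, 50), 2, 2)
    net <- road_network(list(cbind(x = seg[, 1], y = seg[, 2])),
                        covered = TRUE)
    px <- runif(1, -60, 60); py <- runif(1, -60, 60)
    tt <- seq(0, 1, length.out = 20001)
    ox <- seg[1, 1] + tt * (seg[2, 1] - seg[1, 1])
    oy <- seg[1, 2] + tt * (seg[2, 2] - seg[1, 2])
    oracle <- sqrt(min((px - ox)^2 + (py - oy)^2))
    expect_equal(nearest_covered_road_distance(px, py, net), oracle,
                 tolerance = 1e-5)
  }
})

test_that("distance is zero exactly on covered segments", {
  net <- road_network(list(cbind(x = c(0, 30, 60), y = c(0, 20, 10))),
                      covered = TRUE)
  on_road <- cliffscout:::points_along(net$lines[[1]], c(0, 12.5, 40))
  d <- nearest_covered_road_distance(on_road[, 1], on_road[, 2], net)
  expect_true(all(d < 1e-9))
  off <- nearest_covered_road_distance(10, 30, net)
  expect_gt(off, 1e-9)
})

test_that("Welch t from summaries reproduces the published comparisons", {
  expect_equal(welch_t_from_summaries(955, 67, 2170, 210)$t2, 5.51)
  expect_equal(welch_t_from_summaries(1076, 93, 839, 86)$t2, 1.87)
  expect_equal(welch_t_from_summaries(1432, 141, 1336, 140)$t2, 0.48)
  expect_equal(welch_t_from_summaries(10, 1, 10, 2)$t, 0)
})

test_that("Welch t is symmetric in group order and scale-free", {
  set.seed(47)
  for (i in 1:10) {
    m1 <- runif(1, 0, 100); m2 <- runif(1, 0, 100)
    s1 <- runif(1, 0.1, 10); s2 <- runif(1, 0.1, 10)
    k <- runif(1, 0.1, 50)
    expect_equal(welch_t_from_summaries(m1, s1, m2, s2)$t,
                 welch_t_from_summaries(m2, s2, m1, s1)$t)
    expect_equal(welch_t_from_summaries(k * m1, k * s1, k * m2, k * s2)$t,
                 welch_t_from_summaries(m1, s1, m2, s2)$t)
  }
  expect_error(welch_t_from_summaries(1, 0, 2, 1), "positive")
  # df and p emerge when sample sizes are supplied
  full <- welch_t_from_summaries(955, 67, 2170, 210, n1 = 97, n2 = 51)
  expect_true(full$df > 2 && full$df < 146)
  expect_lt(full$p, 0.001)
})

test_that("detection rates round to the published integers", {
  cases <- list(c(97, 148, 66), c(37, 58, 64), c(68, 104, 65),
                c(46, 114, 40), c(25, 88, 28), c(80, 123, 65),
                c(1907, 3905, 49))
  for (cs in cases)
    expect_equal(detection_rate(cs[1], cs[2])$pct_int, cs[3])
  expect_equal(detection_rate(0, 10)$pct, 0)
  expect_error(detection_rate(5, 0), "n > 0")
  expect_error(detection_rate(-1, 10), "0 <= k")
})

test_that("chi-square on 2x2 tables matches hand computation", {
  prop <- chi_square_2x2(10, 20, 30, 60)      # perfectly proportional
  expect_equal(prop$statistic, 0)
  expect_equal(chi_square_2x2(10, 0, 0, 10, yates = FALSE)$statistic, 20)
  a <- chi_square_2x2(37, 21, 68, 36, yates = FALSE)
  b <- chi_square_2x2(68, 36, 37, 21, yates = FALSE)   # rows swapped
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$df, 1)
  expect_error(chi_square_2x2(0, 0, 5, 5), "positive row")
})

test_that("distance summaries use interpolated order statistics", {
  expect_equal(distance_summary(800)$median, 800)
  expect_equal(distance_summary(c(1, 2, 3, 4))$median, 2.5)
  set.seed(53)
  for (i in 1:10) {
    d <- runif(sample(2:30, 1), 0, 4000)
    s <- sort(d); n <- length(d)
    # sort-based oracle with linear interpolation between order statistics
    oracle <- function(p) {
      h <- (n - 1) * p + 1
      s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
    }
    got <- distance_summary(d)
    expect_equal(got$median, oracle(0.5))
    expect_equal(got$p75, oracle(0.75))
  }
  expect_error(distance_summary(numeric(0)), "non-empty")
})

test_that("feature detection table counts field and remote observations", {
  sites <- data.frame(
    has_white_spots = c(TRUE, TRUE, TRUE, FALSE),
    has_cave = c(TRUE, FALSE, FALSE, FALSE),
    has_vegetation = c(TRUE, TRUE, FALSE, TRUE),
    remote_identified = c(TRUE, TRUE, FALSE, FALSE),
    remote_white_spots = c(TRUE, FALSE, FALSE, FALSE),
    remote_cave = c(TRUE, FALSE, FALSE, FALSE),
    remote_vegetation = c(TRUE, TRUE, FALSE, FALSE))
  tab <- feature_detection_table(sites)
  expect_equal(tab$field_n, c(3, 1, 3))
  expect_equal(tab$remote_n, c(1, 1, 2))
  expect_equal(tab$remote_pct_int, c(33L, 100L, 67L))
  expect_true(all(tab$remote_n <= tab$field_n))
  expect_true(all(tab$remote_n <= sum(sites$remote_identified)))

  # everything seen remotely
  all_seen <- sites
  all_seen$remote_identified <- TRUE
  for (f in c("white_spots", "cave", "vegetation"))
    all_seen[[paste0("remote_", f)]] <- all_seen[[paste0("has_", f)]]
  expect_equal(feature_detection_table(all_seen)$remote_pct,
               c(100, 100, 100))

  # nothing identified -> zero detection, absent feature undefined
  none <- sites
  none$remote_identified <- FALSE
  none$remote_white_spots <- FALSE
  none$remote_cave <- FALSE
  none$remote_vegetation <- FALSE
  none$has_cave <- FALSE
  tab0 <- feature_detection_table(none)
  expect_equal(tab0$remote_pct[tab0$feature == "white_spots"], 0)
  expect_true(is.na(tab0$remote_pct[tab0$feature == "cave"]))

  bad <- sites
  bad$remote_vegetation[3] <- TRUE    # remote flag without identification
  expect_error(feature_detection_table(bad), "remote_identified")
})
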