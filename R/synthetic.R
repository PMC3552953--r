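#' Configuration for the synthetic landscape generator
#'
#' Bundles every parameter of the synthetic study system: terrain, scarps
#' (the cliff habitat), a partially imagery-covered road network, nesting
#' sites with fine-scale features, the distance-decay identification
#' process, and per-square survey-effort rates. Defaults reproduce the
#' statistical structure of the field system the package models: 49% of
#' the paved network imagery-covered; feature prevalences 77% (white
#' spots), 59% (caves), 76% (vegetation); remote feature-detection
#' probabilities 0.40/0.28/0.65 conditional on identification; logistic
#' identification with `d50 = 1000` m and scale 150 m (an approximate 1-km
#' identifiability limit); per-km2 time rates 0.91 (remote) and 3.97
#' (ground) min/km2. The landscape is one survey square: a 100 x 100 grid
#' of 100-m cells (10 x 10 km) with smooth base relief and cuesta-shaped
#' scarps whose face gradient (default 0.7) matches observed
#' occupied-cliff slopes.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell side, m.
#' @param base_amplitude,base_wavelength base-relief amplitude (m) and
#'   wavelength (m).
#' @param scarp_count number of linear scarps.
#' @param scarp_height scarp height, m.
#' @param scarp_face_cells scarp face width in cells; the implied face
#'   gradient is `scarp_height / (scarp_face_cells * cell_size)`.
#' @param scarp_backslope_cells width (cells) of the gentle dip slope
#'   behind the scarp crest that returns the surface to base level.
#' @param road_spacing lattice spacing of the road network, m.
#' @param coverage_fraction share (by length) of the paved network with
#'   street-level imagery.
#' @param unpaved_roads also lay the half-offset unpaved lattice that only
#'   the on-ground survey can drive.
#' @param n_nest_sites number of occupied nesting cliffs.
#' @param prev_white_spots,prev_cave,prev_vegetation field prevalences of
#'   the fine-scale features.
#' @param occ_griffon_only,occ_egyptian_only,occ_both species-occupancy
#'   shares (sum <= 1; remainder assigned to griffon).
#' @param limestone_share share of sites on limestone substrate.
#' @param d50 distance (m) at which an otherwise-visible cliff is
#'   identified with probability 1/2.
#' @param logistic_scale scale (m) of the logistic distance decay.
#' @param p_remote_white_spots,p_remote_cave,p_remote_vegetation
#'   probability that a field-recorded feature is also seen remotely,
#'   conditional on the cliff being identified.
#' @param rate_remote_mean,rate_remote_sd remote survey time rate,
#'   min/km2: mean and between-square SD of the lognormal draw.
#' @param rate_ground_mean,rate_ground_sd on-ground analogues.
#' @param seed integer; fixes every downstream draw.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_rows = 100, n_cols = 100, cell_size = 100,
                         base_amplitude = 80, base_wavelength = 2000,
                         scarp_count = 8, scarp_height = 280,
                         scarp_face_cells = 4,
                         scarp_backslope_cells = 16,
                         road_spacing = 3000, coverage_fraction = 0.49,
                         unpaved_roads = TRUE,
                         n_nest_sites = 148,
                         prev_white_spots = 0.77, prev_cave = 0.59,
                         prev_vegetation = 0.76,
                         occ_griffon_only = 44 / 148,
                         occ_egyptian_only = 90 / 148,
                         occ_both = 14 / 148,
                         limestone_share = 0.8,
                         d50 = 1000, logistic_scale = 150,
                         p_remote_white_spots = 0.40,
                         p_remote_cave = 0.28,
                         p_remote_vegetation = 0.65,
                         rate_remote_mean = 0.91, rate_remote_sd = 0.21,
                         rate_ground_mean = 3.97, rate_ground_sd = 2.94,
                         seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$coverage_fraction, cfg$prev_white_spots, cfg$prev_cave,
             cfg$prev_vegetation, cfg$limestone_share,
             cfg$p_remote_white_spots, cfg$p_remote_cave,
             cfg$p_remote_vegetation)
  if (any(fracs < 0 | fracs > 1))
    stop_invalid("fractions must lie in [0, 1]")
  if (cfg$occ_griffon_only + cfg$occ_egyptian_only + cfg$occ_both > 1 + 1e-9)
    stop_invalid("occupancy shares must sum to <= 1")
  lens <- c(cfg$cell_size, cfg$base_wavelength, cfg$road_spacing,
            cfg$d50, cfg$logistic_scale)
  if (any(lens <= 0)) stop_invalid("lengths must be > 0")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic landscape with cliff scarps
#'
#' Builds a smooth low-frequency base surface (a product of sinusoids with
#' seeded random phases) and superimposes `scarp_count` cuesta-shaped
#' scarps in random axis-aligned orientations and positions: each climbs
#' `scarp_height` m over a face `scarp_face_cells` cells wide and dips
#' gently back to base level over `scarp_backslope_cells` cells, running
#' the full extent along its axis. The truth mask marks
#' the interior scarp-face cells — those whose full 3x3 slope window lies
#' on the ramp, where the Horn gradient equals the designed face gradient
#' `scarp_height / (scarp_face_cells * cell_size)` (faces narrower than 3
#' cells therefore yield no truth cells). Deterministic given the config
#' seed.
#'
#' @param cfg a [synth_config()].
#' @return List with `dem` (an [elev_grid()]) and `truth` (0/1
#'   [elev_grid()] of cliff-face cells).
#' @export
make_landscape <- function(cfg) {
  cs <- cfg$cell_size
  nr <- cfg$n_rows; nc <- cfg$n_cols
  face_w <- cfg$scarp_face_cells * cs
  if (face_w >= min(nr, nc) * cs)
    stop_invalid("scarp face wider than the grid extent")
  with_seed(derive_seed(cfg$seed, 1L), {
    x <- (seq_len(nc) - 0.5) * cs
    y <- (nr - seq_len(nr) + 0.5) * cs
    ph <- stats::runif(4, 0, 2 * pi)
    wl <- cfg$base_wavelength
    A <- cfg$base_amplitude
    z <- A * outer(sin(2 * pi * y / wl + ph[1]),
                   sin(2 * pi * x / wl + ph[2])) +
      0.3 * A * outer(sin(4 * pi * y / wl + ph[3]),
                      sin(4 * pi * x / wl + ph[4]))
    truth <- matrix(FALSE, nr, nc)
    # cuesta profile: climb the face over [0, 1] in units of face width,
    # then dip gently back to base level over the backslope
    back <- cfg$scarp_backslope_cells / cfg$scarp_face_cells
    cuesta <- function(raw) {
      g <- pmin(pmax(raw, 0), 1)
      dn <- raw > 1
      g[dn] <- pmax(0, 1 - (raw[dn] - 1) / back)
      g
    }
    margin <- cs / face_w
    used_v <- rep(FALSE, nc)   # face-strip columns taken by N-S scarps
    used_h <- rep(FALSE, nr)   # face-strip rows taken by E-W scarps
    for (k in seq_len(max(cfg$scarp_count, 0))) {
      for (try in 1:40) {
        vertical <- stats::runif(1) < 0.5    # face varies along x
        across <- if (vertical) x else y     # axis the face climbs along
        c0 <- min(across) +
          stats::runif(1) * (max(across) - min(across) - face_w)
        # cliffs and roads avoid each other in real landscapes (roads are
        # built through gentle terrain): keep the face centre at least a
        # quarter road-spacing away from the road lattice parallel to it
        off <- (c0 + face_w / 2) %% cfg$road_spacing
        if (min(off, cfg$road_spacing - off) < 0.25 * cfg$road_spacing)
          next
        raw <- (across - c0) / face_w
        # parallel faces must not overlap: superposed opposing ramps
        # would cancel each other's gradient (perpendicular scarps may
        # cross freely; crossing gradients add in quadrature)
        strip <- raw > -margin & raw < 1 + margin
        used <- if (vertical) used_v else used_h
        if (any(strip & used)) next
        if (vertical) used_v <- used_v | strip
        else used_h <- used_h | strip
        if (stats::runif(1) < 0.5) raw <- 1 - raw   # face E or W / N or S
        g <- cfg$scarp_height * cuesta(raw)
        # truth: interior face cells, where the whole 3x3 slope window
        # lies on the face and the Horn gradient equals the designed
        # face gradient
        face_across <- raw > margin & raw < 1 - margin
        if (vertical) {
          z <- z + matrix(g, nr, nc, byrow = TRUE)
          truth <- truth | matrix(face_across, nr, nc, byrow = TRUE)
        } else {
          z <- z + matrix(g, nr, nc)
          truth <- truth | matrix(face_across, nr, nc)
        }
        break
      }
    }
    # the outer ring has no slope estimate (Horn needs a full 3x3 window),
    # so it cannot carry analyzable cliff cells
    truth[c(1, nr), ] <- FALSE
    truth[, c(1, nc)] <- FALSE
    list(dem = elev_grid(z, cs),
         truth = elev_grid(truth + 0, cs))
  })
}

#' Generate a partially imagery-covered road network
#'
#' Lays a lattice of paved roads at `road_spacing` (with small seeded
#' vertex jitter) plus a half-offset unpaved lattice, chops each line into
#' short polyline pieces, and flags a random subset of the paved pieces as
#' imagery-covered so that the covered share of paved length matches
#' `coverage_fraction` as closely as the piece lengths allow (within about
#' 2% at the defaults). Deterministic given the config seed.
#'
#' @param cfg a [synth_config()].
#' @param grid an [elev_grid()] giving the extent to span.
#' @return A [road_network()].
#' @export
make_roads <- function(cfg, grid) {
  ext <- grid_extent(grid)
  cs <- grid$cell_size
  # keep vertices strictly inside the half-open grid extent so every road
  # point (observers included) maps to a cell
  tiny <- 1e-6
  clamp_xy <- function(m) {
    m[, 1] <- pmin(pmax(m[, 1], ext["xmin"]), ext["xmax"] - tiny)
    m[, 2] <- pmin(pmax(m[, 2], ext["ymin"] + tiny), ext["ymax"])
    m
  }
  # roads keep to gentle terrain: each lattice line is laid at whichever
  # of several parallel candidate positions has the lowest mean slope
  # along its course (mountain roads follow valleys, not cliff faces)
  sg <- tryCatch(terrain_slope(grid), error = function(e) NULL)
  line_score <- function(m) {
    if (is.null(sg)) return(0)
    p <- points_along(m, seq(0, sum(sqrt(diff(m[, 1])^2 +
                                           diff(m[, 2])^2)),
                             length.out = 25))
    s <- elevation_at(sg, p[, 1], p[, 2])
    mean(s, na.rm = TRUE)
  }
  shift_cands <- function(base) {
    if (is.null(sg)) return(0)
    cands <- seq(-0.3, 0.3, by = 0.15) * cfg$road_spacing
    cands
  }
  with_seed(derive_seed(cfg$seed, 2L), {
    make_lattice <- function(offset) {
      lines <- list()
      vstep <- 4 * cs
      jig <- 0.3 * cs
      xs <- seq(ext["xmin"] + offset, ext["xmax"], by = cfg$road_spacing)
      xs <- xs[xs > ext["xmin"] & xs < ext["xmax"]]
      for (x0 in xs) {
        yy <- seq(ext["ymin"], ext["ymax"], by = vstep)
        cand_lines <- lapply(shift_cands(x0), function(s) {
          xx <- x0 + s + c(0, stats::runif(length(yy) - 2, -jig, jig), 0)
          clamp_xy(cbind(x = xx, y = yy))
        })
        best <- which.min(vapply(cand_lines, line_score, numeric(1)))
        lines[[length(lines) + 1L]] <- cand_lines[[best]]
      }
      ys <- seq(ext["ymin"] + offset, ext["ymax"], by = cfg$road_spacing)
      ys <- ys[ys > ext["ymin"] & ys < ext["ymax"]]
      for (y0 in ys) {
        xx <- seq(ext["xmin"], ext["xmax"], by = vstep)
        cand_lines <- lapply(shift_cands(y0), function(s) {
          yy <- y0 + s + c(0, stats::runif(length(xx) - 2, -jig, jig), 0)
          clamp_xy(cbind(x = xx, y = yy))
        })
        best <- which.min(vapply(cand_lines, line_score, numeric(1)))
        lines[[length(lines) + 1L]] <- cand_lines[[best]]
      }
      lines
    }
    chop <- function(m, n_pieces) {
      n <- nrow(m)
      cuts <- unique(round(seq(1, n, length.out = n_pieces + 1)))
      lapply(seq_len(length(cuts) - 1), function(i)
        m[cuts[i]:cuts[i + 1], , drop = FALSE])
    }
    # paved lines are split in two so imagery coverage comes in long
    # contiguous stretches (as street-level imagery does) while the
    # covered length can still be matched to coverage_fraction closely
    paved <- unlist(lapply(make_lattice(0), chop, n_pieces = 2),
                    recursive = FALSE)
    unpaved <- if (isTRUE(cfg$unpaved_roads)) {
      unlist(lapply(make_lattice(cfg$road_spacing / 2), chop,
                    n_pieces = 1),
             recursive = FALSE)
    } else list()
    paved <- lapply(paved, clamp_xy)
    unpaved <- lapply(unpaved, clamp_xy)
    plen <- vapply(paved, function(m)
      sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)), numeric(1))
    target <- cfg$coverage_fraction * sum(plen)
    ord <- sample.int(length(paved))
    covered_flag <- rep(FALSE, length(paved))
    cum <- 0
    for (i in ord) {
      if (cum + plen[i] <= target) {
        covered_flag[i] <- TRUE
        cum <- cum + plen[i]
      } else if (target - cum > 1e-9) {
        # coverage ends part-way along this road: split it there
        split <- split_polyline(paved[[i]], target - cum)
        paved[[i]] <- split$head
        covered_flag[i] <- TRUE
        if (!is.null(split$tail)) {
          paved[[length(paved) + 1L]] <- split$tail
          covered_flag[length(paved)] <- FALSE
        }
        cum <- target
      }
    }
    lines <- c(paved, unpaved)
    covered <- c(covered_flag, rep(FALSE, length(unpaved)))
    surface <- rep(c("paved", "unpaved"),
                   c(length(paved), length(unpaved)))
    road_network(lines, covered, surface)
  })
}

#' Place nesting sites on cliff-face cells
#'
#' Draws `n_nest_sites` cells without replacement from the truth cliff
#' mask, assigns species occupancy by the configured shares, independent
#' fine-scale feature flags by the configured prevalences, and substrate.
#' Remote-observation columns are initialized to `FALSE` and later filled
#' by [simulate_identification()].
#'
#' @param truth 0/1 cliff-face [elev_grid()] from [make_landscape()].
#' @param cfg a [synth_config()].
#' @return Data frame of cliff sites (one row per site).
#' @export
make_nest_sites <- function(truth, cfg) {
  cells <- which(truth$values != 0)
  n <- cfg$n_nest_sites
  if (length(cells) < n)
    stop_invalid("only %d cliff cells for %d nest sites",
                 length(cells), n)
  with_seed(derive_seed(cfg$seed, 3L), {
    pick <- sample_int(cells, n)
    rc <- arrayInd(pick, dim(truth$values))
    nr <- nrow(truth$values); cs <- truth$cell_size
    rest <- max(0, 1 - cfg$occ_griffon_only - cfg$occ_egyptian_only -
                  cfg$occ_both)
    occ <- sample(c("griffon", "egyptian", "both"), n, replace = TRUE,
                  prob = c(cfg$occ_griffon_only + rest,
                           cfg$occ_egyptian_only, cfg$occ_both))
    data.frame(
      id = seq_len(n),
      x = truth$xll + (rc[, 2] - 0.5) * cs,
      y = truth$yll + (nr - rc[, 1] + 0.5) * cs,
      occupied_by_griffon = occ %in% c("griffon", "both"),
      occupied_by_egyptian = occ %in% c("egyptian", "both"),
      has_white_spots = stats::runif(n) < cfg$prev_white_spots,
      has_cave = stats::runif(n) < cfg$prev_cave,
      has_vegetation = stats::runif(n) < cfg$prev_vegetation,
      substrate = ifelse(stats::runif(n) < cfg$limestone_share,
                         "limestone", "non-limestone"),
      remote_identified = FALSE,
      remote_white_spots = FALSE,
      remote_cave = FALSE,
      remote_vegetation = FALSE)
  })
}

#' Simulate remote identification of nesting cliffs
#'
#' A cliff is identified remotely with probability
#' `plogis((d50 - d) / scale)` — distance decay with midpoint `d50` — and
#' only if its cell is visible in the remote viewshed. For identified
#' cliffs, each field-recorded feature is seen remotely with its
#' per-feature conditional probability. Deterministic given the config
#' seed.
#'
#' @param sites data frame from [make_nest_sites()].
#' @param roads a [road_network()] with covered polylines.
#' @param vis 0/1 visibility [elev_grid()] from [viewshed()], or `NULL` to
#'   treat every site as visible.
#' @param cfg a [synth_config()].
#' @return `sites` with `remote_identified`, `remote_*` feature flags and
#'   a `dist_covered_road_m` column filled in.
#' @export
simulate_identification <- function(sites, roads, vis, cfg) {
  d <- nearest_covered_road_distance(sites$x, sites$y, roads)
  visible <- if (is.null(vis)) rep(TRUE, nrow(sites))
             else value_at(vis, sites$x, sites$y) != 0
  with_seed(derive_seed(cfg$seed, 4L), {
    p <- stats::plogis((cfg$d50 - d) / cfg$logistic_scale)
    n <- nrow(sites)
    ident <- visible & (stats::runif(n) < p)
    sites$remote_identified <- ident
    sites$remote_white_spots <- ident & sites$has_white_spots &
      (stats::runif(n) < cfg$p_remote_white_spots)
    sites$remote_cave <- ident & sites$has_cave &
      (stats::runif(n) < cfg$p_remote_cave)
    sites$remote_vegetation <- ident & sites$has_vegetation &
      (stats::runif(n) < cfg$p_remote_vegetation)
    sites$dist_covered_road_m <- d
    sites
  })
}

# lognormal draws matched to a given mean and sd (sd 0 -> constant)
rlnorm_moments <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate per-square survey times
#'
#' Draws per-square per-km2 time rates from lognormal distributions
#' moment-matched to the configured mean and SD (strictly positive by
#' construction), and fills in survey times as rate times viewshed area.
#'
#' @param squares data frame with columns `viewshed_ground_km2` and
#'   `viewshed_remote_km2` (one row per survey square).
#' @param cfg a [synth_config()].
#' @return `squares` with `rate_ground`, `rate_remote` (min/km2),
#'   `time_ground_min` and `time_remote_min` columns added.
#' @export
simulate_survey_times <- function(squares, cfg) {
  n <- nrow(squares)
  with_seed(derive_seed(cfg$seed, 5L), {
    squares$rate_ground <- rlnorm_moments(n, cfg$rate_ground_mean,
                                          cfg$rate_ground_sd)
    squares$rate_remote <- rlnorm_moments(n, cfg$rate_remote_mean,
                                          cfg$rate_remote_sd)
    squares$time_ground_min <- squares$rate_ground *
      squares$viewshed_ground_km2
    squares$time_remote_min <- squares$rate_remote *
      squares$viewshed_remote_km2
    squares
  })
}

#' Fit the logistic distance-decay identification model
#'
#' Maximum-likelihood logistic regression of identification outcome on
#' distance (via [stats::glm()]), reparameterized to the midpoint/scale
#' form `p(d) = plogis((d50 - d) / scale)` used by
#' [simulate_identification()].
#'
#' @param distance numeric vector of distances to the nearest covered
#'   road (m).
#' @param identified logical vector of identification outcomes.
#' @return List with `d50` and `scale` estimates.
#' @export
fit_distance_decay <- function(distance, identified) {
  fit <- stats::glm(identified ~ distance, family = stats::binomial())
  b <- stats::coef(fit)
  if (b[2] >= 0)
    warning("fitted identification probability does not decay with distance")
  list(d50 = unname(-b[1] / b[2]), scale = unname(-1 / b[2]))
}
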