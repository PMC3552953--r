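#' Default end-to-end analysis configuration
#'
#' A complete configuration for [run_full_analysis()] on synthetic data:
#' the synthetic-landscape settings (see [synth_config()]), viewshed
#' observer settings, ground-truth sampling design (100 points, 50 cliff +
#' 50 non-cliff, stratified over a 2 x 2 division of the extent into
#' survey squares), and survey cost constants (30 km/h, 0.19 euro/km).
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @return Nested list of class `cliffscout_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synth = list(),
    viewshed = list(eye_height = 2.5, target_height = 0,
                    observer_spacing = 300, max_distance = Inf),
    accuracy = list(n_cliff = 50, n_noncliff = 50, strata_dim = c(2L, 2L)),
    economics = list(ground_speed = 30, euro_per_km = 0.19)
  ), class = "cliffscout_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path file path.
#' @return `read_config()` returns a `cliffscout_config` list (unspecified
#'   keys filled from [default_config()]).
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(if (is.null(raw$seed)) 1L else raw$seed)
  for (sec in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[sec]])) {
      for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
    } else {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  # JSON has no Inf literal; jsonlite round-trips it as the string "Inf"
  cfg$viewshed$max_distance <- as.numeric(cfg$viewshed$max_distance)
  cfg
}

#' @param config a `cliffscout_config` list.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# 2 x 2 (or m x n) block masks dividing the grid into survey squares
stratum_masks <- function(grid, dims) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rbreaks <- round(seq(0, nr, length.out = dims[1] + 1))
  cbreaks <- round(seq(0, nc, length.out = dims[2] + 1))
  masks <- list()
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      m <- matrix(FALSE, nr, nc)
      m[(rbreaks[i] + 1):rbreaks[i + 1],
        (cbreaks[j] + 1):cbreaks[j + 1]] <- TRUE
      masks[[length(masks) + 1L]] <- m
    }
  }
  masks
}

# road length (m) inside each stratum, by segment midpoint ownership
road_km_by_stratum <- function(net, grid, masks, covered_only = FALSE,
                               surface = NULL) {
  keep <- if (covered_only) net$covered else rep(TRUE, length(net$lines))
  if (!is.null(surface)) keep <- keep & net$surface == surface
  km <- numeric(length(masks))
  for (i in which(keep)) {
    m <- net$lines[[i]]
    n <- nrow(m)
    mx <- (m[-n, 1] + m[-1, 1]) / 2
    my <- (m[-n, 2] + m[-1, 2]) / 2
    len <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    for (s in seq_along(masks)) {
      inside <- vapply(seq_along(mx), function(k) {
        rc <- point_to_cell(grid, mx[k], my[k])
        masks[[s]][rc[1], rc[2]]
      }, logical(1))
      km[s] <- km[s] + sum(len[inside]) / 1000
    }
  }
  km
}

#' Run the full cliff-habitat analysis pipeline
#'
#' Executes every stage on a synthetic landscape: terrain generation,
#' slope, road network, ground and remote observer sets and their
#' viewsheds, slope thresholds from occupied nesting cliffs, the three
#' candidate-cliff maps, stratified ground-truth sampling and the accuracy
#' table, the per-square survey economics table, and the
#' detectability/feature analysis. All randomness derives from
#' `config$seed`, so outputs are a pure function of the configuration.
#'
#' @param config a `cliffscout_config` from [default_config()] or
#'   [read_config()].
#' @param out_dir optional directory; when given, every table, grid and a
#'   run manifest are written there (see [render_reports()]).
#' @param quiet suppress per-stage progress messages.
#' @return List with elements `dem`, `slopes`, `truth`, `roads`,
#'   `vis_ground`, `vis_remote`, `thresholds`, `maps`, `ground_truth`,
#'   `accuracy`, `squares`, `savings`, `economics_tests`, `sites`,
#'   `detect`, and `manifest`.
#' @export
run_full_analysis <- function(config = default_config(), out_dir = NULL,
                              quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  scfg <- do.call(synth_config, c(config$synth, list(seed = config$seed)))

  say("stage terrain: %d x %d cells at %g m", scfg$n_rows, scfg$n_cols,
      scfg$cell_size)
  land <- make_landscape(scfg)
  slopes <- terrain_slope(land$dem)

  say("stage roads")
  roads <- make_roads(scfg, land$dem)

  vcfg <- config$viewshed
  obs_ground <- observers_along_roads(roads, vcfg$observer_spacing,
                                      covered_only = FALSE,
                                      eye_height = vcfg$eye_height)
  obs_remote <- observers_along_roads(roads, vcfg$observer_spacing,
                                      covered_only = TRUE,
                                      eye_height = vcfg$eye_height)
  say("stage viewshed: %d ground / %d remote observers",
      nrow(obs_ground), nrow(obs_remote))
  vis_ground <- viewshed(land$dem, obs_ground, vcfg$max_distance,
                         vcfg$target_height)
  vis_remote <- viewshed(land$dem, obs_remote, vcfg$max_distance,
                         vcfg$target_height)

  say("stage classification")
  sites <- make_nest_sites(land$truth, scfg)
  thr <- slope_thresholds(occupied_slope_sample(slopes, sites))
  maps <- list(s_min = classify_cliffs(slopes, thr$s_min),
               s_25 = classify_cliffs(slopes, thr$s_25),
               s_50 = classify_cliffs(slopes, thr$s_50))

  say("stage accuracy assessment")
  masks <- stratum_masks(land$dem, config$accuracy$strata_dim)
  # slope is nodata on the outer ring; restrict reference sampling to the
  # remotely surveyed area with valid slope, as in the field protocol
  valid <- !is.na(slopes$values)
  region <- valid & vis_remote$values != 0
  gt <- sample_ground_truth(land$truth, config$accuracy$n_cliff,
                            config$accuracy$n_noncliff,
                            strata = masks, region_mask = region,
                            seed = derive_seed(config$seed, 6L),
                            strict = FALSE)
  acc <- accuracy_report(maps, gt)

  say("stage survey economics")
  params <- cost_params(config$economics$ground_speed,
                        config$economics$euro_per_km)
  cell_km2 <- (land$dem$cell_size / 1000)^2
  squares <- data.frame(
    square_id = seq_along(masks),
    area_km2 = vapply(masks, sum, numeric(1)) * cell_km2,
    road_km_ground = road_km_by_stratum(roads, land$dem, masks),
    road_km_covered = road_km_by_stratum(roads, land$dem, masks,
                                         covered_only = TRUE),
    viewshed_ground_km2 = vapply(masks, function(m)
      sum(vis_ground$values[m] != 0), numeric(1)) * cell_km2,
    viewshed_remote_km2 = vapply(masks, function(m)
      sum(vis_remote$values[m] != 0), numeric(1)) * cell_km2)
  squares <- simulate_survey_times(squares, scfg)
  squares$cost_ground_euro <- ground_cost(squares$road_km_ground, params)
  squares$rate_cost <- per_area_rate(squares$cost_ground_euro,
                                     squares$viewshed_ground_km2)
  savings <- combined_savings(squares$viewshed_ground_km2,
                              squares$viewshed_remote_km2,
                              squares$rate_ground, squares$rate_remote,
                              squares$rate_cost)
  # degenerate comparisons (e.g. identical viewsheds under full imagery
  # coverage) are reported as absent rather than aborting the run
  econ_tests <- list(
    wilcoxon_time = tryCatch(
      wilcoxon_signed_rank(squares$rate_remote, squares$rate_ground),
      error = function(e) NULL),
    paired_t_viewshed = tryCatch(
      paired_t(100 * squares$viewshed_remote_km2 / squares$area_km2,
               100 * squares$viewshed_ground_km2 / squares$area_km2),
      error = function(e) NULL))

  say("stage detectability")
  sites <- simulate_identification(sites, roads, vis_remote, scfg)
  id_d <- sites$dist_covered_road_m[sites$remote_identified]
  un_d <- sites$dist_covered_road_m[!sites$remote_identified]
  welch <- if (length(id_d) >= 2 && length(un_d) >= 2) {
    welch_t_from_summaries(
      mean(id_d), stats::sd(id_d) / sqrt(length(id_d)),
      mean(un_d), stats::sd(un_d) / sqrt(length(un_d)),
      n1 = length(id_d), n2 = length(un_d))
  } else NULL
  detect <- list(
    n_sites = nrow(sites),
    rate_total = detection_rate(sum(sites$remote_identified), nrow(sites)),
    features = feature_detection_table(sites),
    distance_summary = if (length(id_d))
      distance_summary(id_d) else NULL,
    welch_identified_vs_not = welch)

  results <- list(dem = land$dem, slopes = slopes, truth = land$truth,
                  roads = roads, vis_ground = vis_ground,
                  vis_remote = vis_remote, thresholds = thr, maps = maps,
                  ground_truth = gt, accuracy = acc, squares = squares,
                  savings = savings, economics_tests = econ_tests,
                  sites = sites, detect = detect)
  results$manifest <- run_manifest(config, results, t0)
  if (!is.null(out_dir)) render_reports(results, out_dir)
  results
}

run_manifest <- function(config, results, t0) {
  key_numbers <- list(
    thresholds = unclass(results$thresholds),
    accuracy = results$accuracy,
    pct_cost = results$savings$pct_cost,
    rate_total_pct = results$detect$rate_total$pct)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(config = unclass(config),
                            results = key_numbers),
                       tmp, auto_unbox = TRUE, digits = 12)
  list(seed = config$seed,
       hash = unname(tools::md5sum(tmp)),
       package_version = as.character(utils::packageVersion("cliffscout")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

fmt_pct <- function(x) as.character(round(x))
fmt_rate <- function(x) sprintf("%.2f", x)

#' Write the pipeline report tables
#'
#' Renders three CSVs mirroring the published table layouts — per-square
#' survey effort (times/costs per km2 of viewshed), map accuracy (one
#' column per method; percentages as integers, error rates and kappa to
#' two decimals), and feature detection — plus the raw site table, the
#' cliff maps and viewsheds as ESRI ASCII grids, the roads as GeoJSON and
#' a JSON manifest.
#'
#' @param results list from [run_full_analysis()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_reports <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acc <- results$accuracy
  fmt <- acc
  pctrows <- grepl("accuracy$", acc$metric)
  raterows <- grepl("rate$|kappa$", acc$metric)
  for (col in names(acc)[-1]) {
    fmt[[col]] <- as.character(acc[[col]])
    fmt[[col]][pctrows] <- fmt_pct(acc[[col]][pctrows])
    fmt[[col]][raterows] <- fmt_rate(acc[[col]][raterows])
  }
  utils::write.csv(fmt, file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)

  sq <- results$squares
  econ <- data.frame(
    metric = c("viewshed_pct", "time_min_per_km2", "cost_euro_per_km2"),
    on_ground = fmt_rate(c(
      mean(100 * sq$viewshed_ground_km2 / sq$area_km2),
      mean(sq$rate_ground), mean(sq$rate_cost))),
    street_view = fmt_rate(c(
      mean(100 * sq$viewshed_remote_km2 / sq$area_km2),
      mean(sq$rate_remote), 0)),
    combined = fmt_rate(c(
      mean(100 * sq$viewshed_ground_km2 / sq$area_km2),
      mean((sq$time_ground_min - results$savings$time_saved_min) /
             sq$viewshed_ground_km2),
      mean((sq$cost_ground_euro - results$savings$cost_saved_euro) /
             sq$viewshed_ground_km2))))
  utils::write.csv(econ, file.path(out_dir, "economics.csv"),
                   row.names = FALSE)
  utils::write.csv(sq, file.path(out_dir, "squares.csv"),
                   row.names = FALSE)

  feat <- results$detect$features
  feat$remote_pct <- ifelse(is.na(feat$remote_pct), "",
                            fmt_pct(feat$remote_pct))
  utils::write.csv(feat[, c("feature", "field_n", "remote_n",
                            "remote_pct")],
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(results$sites, file.path(out_dir, "sites.csv"),
                   row.names = FALSE)
  utils::write.csv(results$ground_truth,
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)

  write_esri_ascii(results$dem, file.path(out_dir, "dem.asc"))
  for (nm in names(results$maps))
    write_esri_ascii(results$maps[[nm]],
                     file.path(out_dir, paste0("map_", nm, ".asc")))
  write_esri_ascii(results$vis_ground,
                   file.path(out_dir, "viewshed_ground.asc"))
  write_esri_ascii(results$vis_remote,
                   file.path(out_dir, "viewshed_remote.asc"))
  write_roads_geojson(results$roads, file.path(out_dir, "roads.geojson"))
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
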