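#' Road network of polylines
#'
#' A `road_network` holds a set of planar polylines, each with a surface
#' class (`"paved"` / `"unpaved"`) and a flag saying whether street-level
#' imagery covers it. It is the source of viewshed observers and of
#' cliff-to-road distances.
#'
#' @param lines list of numeric matrices, one per polyline, each with
#'   columns `x, y` (m) and at least 2 vertices.
#' @param covered logical vector, one per polyline: street-level imagery
#'   available.
#' @param surface character vector, one per polyline: `"paved"` or
#'   `"unpaved"`.
#' @return An object of class `road_network`.
#' @export
road_network <- function(lines,
                         covered = rep(FALSE, length(lines)),
                         surface = rep("paved", length(lines))) {
  if (!is.list(lines))
    stop_invalid("`lines` must be a list of coordinate matrices")
  lines <- lapply(lines, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L || nrow(m) < 2L || !all(is.finite(m)))
      stop_invalid("each polyline needs >= 2 finite (x, y) vertices")
    colnames(m) <- c("x", "y")
    storage.mode(m) <- "double"
    m
  })
  if (length(covered) != length(lines) || !is.logical(covered) ||
      anyNA(covered))
    stop_invalid("`covered` must be a logical flag per polyline")
  if (length(surface) != length(lines) ||
      !all(surface %in% c("paved", "unpaved")))
    stop_invalid("`surface` must be 'paved' or 'unpaved' per polyline")
  structure(list(lines = lines, covered = covered,
                 surface = as.character(surface)),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  lens <- polyline_lengths(x)
  cat(sprintf("<road_network> %d polylines, %.2f km total\n",
              length(x$lines), sum(lens) / 1000))
  cat(sprintf("  paved %.2f km (%.2f km imagery-covered), unpaved %.2f km\n",
              sum(lens[x$surface == "paved"]) / 1000,
              sum(lens[x$covered]) / 1000,
              sum(lens[x$surface == "unpaved"]) / 1000))
  invisible(x)
}

segment_table <- function(net, covered_only = FALSE) {
  keep <- if (covered_only) which(net$covered) else seq_along(net$lines)
  if (!length(keep))
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1"))))
  segs <- lapply(keep, function(i) {
    m <- net$lines[[i]]
    n <- nrow(m)
    cbind(x0 = m[-n, 1], y0 = m[-n, 2], x1 = m[-1, 1], y1 = m[-1, 2])
  })
  do.call(rbind, segs)
}

#' Polyline lengths
#'
#' @param net a [road_network()].
#' @return Numeric vector of arc lengths (m), one per polyline.
#' @export
polyline_lengths <- function(net) {
  vapply(net$lines, function(m) {
    sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
  }, numeric(1))
}

#' Total road length
#'
#' @param net a [road_network()].
#' @param covered_only count only imagery-covered polylines.
#' @param surface optionally restrict to `"paved"` or `"unpaved"`.
#' @return Total length in metres.
#' @export
road_length <- function(net, covered_only = FALSE, surface = NULL) {
  keep <- if (covered_only) net$covered else rep(TRUE, length(net$lines))
  if (!is.null(surface)) keep <- keep & net$surface == surface
  sum(polyline_lengths(net)[keep])
}

# split one polyline at arc length `at`; tail is NULL if `at` reaches the end
split_polyline <- function(m, at) {
  seg_len <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  if (at >= total - 1e-9) return(list(head = m, tail = NULL))
  if (at <= 1e-9) stop_invalid("cannot split polyline at its start")
  p <- points_along(m, at)
  i <- findInterval(at, cum, rightmost.closed = TRUE)
  head <- rbind(m[seq_len(i), , drop = FALSE], p)
  tail <- rbind(p, m[seq.int(i + 1, nrow(m)), , drop = FALSE])
  list(head = head, tail = tail)
}

# points at given arc-length positions along one polyline
points_along <- function(m, at) {
  seg_len <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  at <- pmin(pmax(at, 0), total)
  idx <- findInterval(at, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg_len))
  f <- ifelse(seg_len[idx] > 0, (at - cum[idx]) / seg_len[idx], 0)
  cbind(x = m[idx, 1] + f * (m[idx + 1, 1] - m[idx, 1]),
        y = m[idx, 2] + f * (m[idx + 1, 2] - m[idx, 2]))
}

#' Place viewshed observers along roads
#'
#' Discretizes the selected polylines at fixed arc-length intervals; both
#' endpoints of every polyline are always included, so no stretch of road
#' longer than `spacing` is left unobserved.
#'
#' @param net a [road_network()].
#' @param spacing observer spacing along the road, metres (> 0).
#' @param covered_only use only imagery-covered polylines (street-level
#'   imagery survey) rather than the whole drivable network.
#' @param eye_height observer eye height above ground, metres. The default
#'   2.5 m corresponds to a vehicle-mounted camera.
#' @return Data frame with columns `x`, `y`, `eye_height` (possibly 0
#'   rows).
#' @export
observers_along_roads <- function(net, spacing, covered_only = FALSE,
                                  eye_height = 2.5) {
  if (!is_number(spacing) || spacing <= 0)
    stop_invalid("`spacing` must be a positive length in metres")
  if (!is_number(eye_height) || eye_height < 0)
    stop_invalid("`eye_height` must be >= 0")
  keep <- if (covered_only) which(net$covered) else seq_along(net$lines)
  pts <- lapply(keep, function(i) {
    m <- net$lines[[i]]
    total <- sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
    at <- unique(c(seq(0, total, by = spacing), total))
    points_along(m, at)
  })
  if (!length(pts))
    return(data.frame(x = numeric(0), y = numeric(0),
                      eye_height = numeric(0)))
  xy <- do.call(rbind, pts)
  data.frame(x = xy[, 1], y = xy[, 2], eye_height = eye_height)
}

# minimum distance from each point to a set of segments (m)
point_segment_distance <- function(x, y, segs) {
  if (!nrow(segs)) return(rep(Inf, length(x)))
  vapply(seq_along(x), function(i) {
    dx <- segs[, "x1"] - segs[, "x0"]
    dy <- segs[, "y1"] - segs[, "y0"]
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0,
                ((x[i] - segs[, "x0"]) * dx + (y[i] - segs[, "y0"]) * dy) /
                  len2, 0)
    t <- pmin(pmax(t, 0), 1)
    px <- segs[, "x0"] + t * dx
    py <- segs[, "y0"] + t * dy
    sqrt(min((x[i] - px)^2 + (y[i] - py)^2))
  }, numeric(1))
}

#' Distance to the nearest imagery-covered road
#'
#' Minimum Euclidean point-to-segment distance from each point to any
#' polyline flagged as imagery-covered.
#'
#' @param x,y numeric vectors of planar coordinates (m).
#' @param net a [road_network()] with at least one covered polyline.
#' @return Numeric vector of distances in metres.
#' @export
nearest_covered_road_distance <- function(x, y, net) {
  segs <- segment_table(net, covered_only = TRUE)
  if (!nrow(segs))
    stop_invalid("no imagery-covered roads in the network")
  point_segment_distance(x, y, segs)
}

#' Read / write road networks as GeoJSON
#'
#' Roads are stored as a `FeatureCollection` of `LineString` features with
#' `covered` (logical) and `surface` properties, in the planar coordinate
#' system of the analysis.
#'
#' @param path file path.
#' @return `read_roads_geojson()` returns a [road_network()];
#'   `write_roads_geojson()` returns `path` invisibly.
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features))
    stop_invalid("not a GeoJSON FeatureCollection: %s", path)
  feats <- gj$features
  lines <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "LineString"))
      stop_invalid("only LineString features are supported")
    do.call(rbind, lapply(f$geometry$coordinates, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  })
  covered <- vapply(feats, function(f)
    isTRUE(f$properties$covered), logical(1))
  surface <- vapply(feats, function(f) {
    s <- f$properties$surface
    if (is.null(s)) "paved" else as.character(s)
  }, character(1))
  road_network(lines, covered, surface)
}

#' @param net a [road_network()].
#' @rdname read_roads_geojson
#' @export
write_roads_geojson <- function(net, path) {
  feats <- lapply(seq_along(net$lines), function(i) {
    m <- net$lines[[i]]
    list(type = "Feature",
         properties = list(covered = net$covered[i],
                           surface = net$surface[i]),
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(m)), function(r)
             c(m[r, 1], m[r, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
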