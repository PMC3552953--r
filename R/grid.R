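#' Regular elevation grid
#'
#' An `elev_grid` is a regular, square-celled raster in projected planar
#' coordinates (metres). Row 1 is the northernmost row and column 1 the
#' westernmost column; `(xll, yll)` is the outer corner of the lower-left
#' cell. Missing terrain is stored as `NA` internally and written out as the
#' `nodata` sentinel.
#'
#' @param values numeric matrix of cell values (elevations in m, slopes as
#'   dimensionless gradients, or 0/1 indicators); `NA` marks nodata cells.
#' @param cell_size side length of a (square) cell in metres.
#' @param xll,yll planar coordinates (m) of the outer corner of the
#'   lower-left cell.
#' @param nodata sentinel written for `NA` cells in ESRI ASCII output.
#' @return An object of class `elev_grid`.
#' @examples
#' g <- elev_grid(matrix(1:4, 2, 2), cell_size = 10)
#' cell_center(g, 1, 1)
#' @export
elev_grid <- function(values, cell_size, xll = 0, yll = 0, nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_invalid("grid must have at least one row and one column")
  if (!is_number(cell_size) || cell_size <= 0)
    stop_invalid("`cell_size` must be a positive number")
  if (any(!is.finite(values) & !is.na(values)))
    stop_invalid("cells must be finite or NA (nodata)")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         nodata = as.numeric(nodata)),
    class = "elev_grid")
}

#' @export
print.elev_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<elev_grid> %d x %d cells, cell size %g m\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$xll, x$xll + ncol(v) * x$cell_size,
              x$yll, x$yll + nrow(v) * x$cell_size))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(fin), max(fin), sum(is.na(v))))
  else cat("  values: all nodata\n")
  invisible(x)
}

#' @export
dim.elev_grid <- function(x) dim(x$values)

#' Grid extent
#'
#' @param grid an [elev_grid()].
#' @return Named numeric vector `xmin, xmax, ymin, ymax` in metres.
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$xll, xmax = grid$xll + ncol(grid$values) * grid$cell_size,
    ymin = grid$yll, ymax = grid$yll + nrow(grid$values) * grid$cell_size)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$cell_size, a$xll, a$yll),
                     c(b$cell_size, b$xll, b$yll)))
}

#' Cell centre coordinates
#'
#' @param grid an [elev_grid()].
#' @param row,col 1-based indices (row 1 is the northernmost row).
#' @return Named numeric vector `x, y` (m) of the cell centre.
#' @export
cell_center <- function(grid, row, col) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (any(row < 1L | row > nr) || any(col < 1L | col > nc))
    stop_invalid("cell index out of range")
  cs <- grid$cell_size
  c(x = grid$xll + (col - 0.5) * cs,
    y = grid$yll + (nr - row + 0.5) * cs)
}

#' Locate the cell containing a point
#'
#' Cell ownership is half-open so every in-extent point maps to exactly one
#' cell: a point on a shared vertical edge belongs to the eastern (larger
#' column) cell and a point on a shared horizontal edge to the southern
#' (larger row) cell. Consequently the extent is `[xmin, xmax)` in x and
#' `(ymin, ymax]` in y.
#'
#' @param grid an [elev_grid()].
#' @param x,y planar coordinates (m).
#' @return Named integer vector `row, col`.
#' @export
point_to_cell <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  ytop <- grid$yll + nr * cs
  col <- floor((x - grid$xll) / cs) + 1
  row <- floor((ytop - y) / cs) + 1
  # a point exactly on the top edge belongs to row 1
  row[y == ytop] <- 1L
  if (any(col < 1 | col > nc | row < 1 | row > nr))
    stop_invalid("point (%g, %g) outside grid extent", x[1], y[1])
  c(row = as.integer(row), col = as.integer(col))
}

#' Nearest-cell raster value at a point
#'
#' @inheritParams point_to_cell
#' @return The value of the cell containing the point (`NA` for nodata).
#' @export
value_at <- function(grid, x, y) {
  rc <- vapply(seq_along(x), function(i)
    point_to_cell(grid, x[i], y[i]), integer(2))
  grid$values[cbind(rc[1L, ], rc[2L, ])]
}

#' Bilinear terrain elevation at arbitrary points
#'
#' Interpolates bilinearly between the four surrounding cell centres;
#' coordinates outside the hull of cell centres are clamped to it (constant
#' extrapolation within the half-cell margin). Any nodata corner makes the
#' result `NA`.
#'
#' @param grid an [elev_grid()].
#' @param x,y numeric vectors of planar coordinates (m).
#' @return Numeric vector of interpolated values.
#' @export
elevation_at <- function(grid, x, y) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v); cs <- grid$cell_size
  xc1 <- grid$xll + 0.5 * cs                 # centre of column 1
  yc1 <- grid$yll + (nr - 0.5) * cs          # centre of row 1 (north)
  u <- (x - xc1) / cs                        # column offset from col-1 centre
  w <- (yc1 - y) / cs                        # row offset from row-1 centre
  u <- pmin(pmax(u, 0), nc - 1)
  w <- pmin(pmax(w, 0), nr - 1)
  j <- pmin(floor(u) + 1, max(nc - 1, 1))
  i <- pmin(floor(w) + 1, max(nr - 1, 1))
  fx <- u - (j - 1)
  fy <- w - (i - 1)
  j2 <- pmin(j + 1, nc); i2 <- pmin(i + 1, nr)
  z11 <- v[cbind(i, j)];  z12 <- v[cbind(i, j2)]
  z21 <- v[cbind(i2, j)]; z22 <- v[cbind(i2, j2)]
  (1 - fy) * ((1 - fx) * z11 + fx * z12) +
    fy * ((1 - fx) * z21 + fx * z22)
}

#' Read an ESRI ASCII Grid
#'
#' Parses the standard `ncols/nrows/xllcorner/yllcorner/cellsize` header
#' (case-insensitive, optional `NODATA_value`) followed by one line of
#' values per raster row, north row first. Nodata cells become `NA`.
#'
#' @param path path to an ESRI ASCII Grid (`.asc`) file.
#' @return An [elev_grid()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+\\S", lines[i]) &&
         !grepl("^\\s*[-+0-9.]", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(tok[1])
    if (!key %in% c(required, "nodata_value"))
      stop_invalid("unsupported ESRI ASCII header key '%s'", tok[1])
    if (length(tok) != 2L || is.na(suppressWarnings(as.numeric(tok[2]))))
      stop_invalid("malformed ESRI ASCII header line for key '%s'", tok[1])
    hdr[[key]] <- as.numeric(tok[2])
    i <- i + 1L
  }
  missing <- setdiff(required, names(hdr))
  if (length(missing))
    stop_invalid("missing ESRI ASCII header key '%s'", missing[1])
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(body) != nrows)
    stop_invalid("expected %d data rows, found %d", nrows, length(body))
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != ncols || anyNA(row))
      stop_invalid("data row %d has %d values, expected %d",
                   r, length(row), ncols)
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  elev_grid(vals, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, nodata)
}

#' Write an ESRI ASCII Grid
#'
#' Round-trips with [read_esri_ascii()]: values, geometry and the nodata
#' mask are preserved exactly (`NA` cells are written as the grid's nodata
#' sentinel).
#'
#' @param grid an [elev_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  v <- grid$values
  num <- function(x) sprintf("%.10g", x)
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", num(grid$xll)),
           paste("yllcorner", num(grid$yll)),
           paste("cellsize", num(grid$cell_size)),
           paste("NODATA_value", num(grid$nodata)))
  vv <- v
  vv[is.na(vv)] <- grid$nodata
  rows <- apply(vv, 1L, function(r) paste(num(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
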