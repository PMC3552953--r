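#' Two-class confusion matrix
#'
#' Counts for a cliff / non-cliff map assessed against reference (ground
#' truth) points: `tp` reference cliffs mapped cliff, `fn` reference cliffs
#' mapped non-cliff, `fp` reference non-cliffs mapped cliff, `tn` reference
#' non-cliffs mapped non-cliff.
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @return Object of class `confusion_2x2`.
#' @export
confusion_2x2 <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts))
    stop_invalid("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  cat("confusion matrix (reference x map):\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("ref cliff", "ref non-cliff"),
                              c("map cliff", "map non-cliff")))
  print(m)
  invisible(x)
}

#' Assess a cliff map against ground-truth points
#'
#' @param map_grid a 0/1 cliff [elev_grid()], e.g. from
#'   [classify_cliffs()].
#' @param points data frame of ground-truth points with columns `x`, `y`
#'   and `true_class` (`"cliff"` / `"non-cliff"`), e.g. from
#'   [sample_ground_truth()].
#' @return A [confusion_2x2()].
#' @export
evaluate_map <- function(map_grid, points) {
  if (!all(points$true_class %in% c("cliff", "non-cliff")))
    stop_invalid("true_class must be 'cliff' or 'non-cliff'")
  mapped <- value_at(map_grid, points$x, points$y) != 0
  truth <- points$true_class == "cliff"
  confusion_2x2(tp = sum(truth & mapped), fn = sum(truth & !mapped),
                fp = sum(!truth & mapped), tn = sum(!truth & !mapped))
}

n_total <- function(cm) cm$tp + cm$fn + cm$fp + cm$tn

#' Accuracy metrics for a two-class map
#'
#' The standard thematic-map accuracy metrics, reported as percentages
#' (0-100) or rates (0-1):
#' * `overall_accuracy()` — correctly classified points / all points.
#' * `producers_accuracy()` — reference points of a class that the map
#'   assigns to that class (complement of the omission error).
#' * `users_accuracy()` — under the standard `"map"` convention, map points
#'   of a class that truly belong to it (`tp/(tp+fp)` for cliffs); under
#'   the `"reference"` convention, the complement of the
#'   reference-relative commission error (`1 - fp/(fp+tn)`).
#' * `omission_error_rate()` — false-negative rate `fn/(tp+fn)`.
#' * `commission_error_rate()` — false positives relative to reference
#'   non-cliffs (`fp/(fp+tn)`, `"reference"`, the default) or to mapped
#'   cliffs (`fp/(tp+fp)`, `"map"`).
#'
#' Both user's-accuracy/commission conventions are provided because
#' published cliff-map assessments use the reference-relative pair (e.g. a
#' map with `tp 49, fn 1, fp 5, tn 45` reported as user's accuracy 90 and
#' commission 0.10, where the map-relative pair gives 90.74 and 0.093).
#'
#' @param cm a [confusion_2x2()].
#' @param class `"cliff"` or `"non-cliff"`.
#' @param convention `"reference"` or `"map"` (see Details).
#' @return A percentage (accuracies) or a rate in `[0, 1]` (error rates).
#' @name accuracy_metrics
NULL

ratio_pct <- function(num, den, what) {
  if (den == 0) stop_invalid("undefined ratio: no %s", what)
  100 * num / den
}

#' @rdname accuracy_metrics
#' @export
overall_accuracy <- function(cm) {
  ratio_pct(cm$tp + cm$tn, n_total(cm), "points")
}

#' @rdname accuracy_metrics
#' @export
producers_accuracy <- function(cm, class = "cliff") {
  if (class == "cliff") ratio_pct(cm$tp, cm$tp + cm$fn, "reference cliffs")
  else ratio_pct(cm$tn, cm$fp + cm$tn, "reference non-cliffs")
}

#' @rdname accuracy_metrics
#' @export
users_accuracy <- function(cm, class = "cliff",
                           convention = c("reference", "map")) {
  convention <- match.arg(convention)
  if (class == "cliff") {
    if (convention == "map")
      ratio_pct(cm$tp, cm$tp + cm$fp, "mapped cliffs")
    else
      100 - 100 * cm$fp / check_pos(cm$fp + cm$tn, "reference non-cliffs")
  } else {
    if (convention == "map")
      ratio_pct(cm$tn, cm$fn + cm$tn, "mapped non-cliffs")
    else
      100 - 100 * cm$fn / check_pos(cm$tp + cm$fn, "reference cliffs")
  }
}

check_pos <- function(x, what) {
  if (x == 0) stop_invalid("undefined ratio: no %s", what)
  x
}

#' @rdname accuracy_metrics
#' @export
omission_error_rate <- function(cm) {
  cm$fn / check_pos(cm$tp + cm$fn, "reference cliffs")
}

#' @rdname accuracy_metrics
#' @export
commission_error_rate <- function(cm, convention = c("reference", "map")) {
  convention <- match.arg(convention)
  if (convention == "reference")
    cm$fp / check_pos(cm$fp + cm$tn, "reference non-cliffs")
  else cm$fp / check_pos(cm$tp + cm$fp, "mapped cliffs")
}

#' Cohen's kappa for a two-class confusion matrix
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with observed
#' agreement `po = (tp + tn) / N` and expected chance agreement
#' `pe = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / N^2`. When the reference
#' classes are balanced (`tp+fn = fp+tn`), `pe = 1/2` and kappa reduces to
#' `2 po - 1`.
#'
#' @param cm a [confusion_2x2()].
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  n <- n_total(cm)
  if (n == 0) stop_invalid("empty confusion matrix")
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
           (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (pe >= 1) {
    if (po == 1) return(1)
    stop_invalid("kappa undefined: chance agreement is 1")
  }
  (po - pe) / (1 - pe)
}

# largest-remainder apportionment of n items over k strata; extras for the
# two classes are assigned from opposite ends so per-stratum totals differ
# by at most one.
apportion <- function(n, k, from_end = FALSE) {
  base <- n %/% k
  extra <- n %% k
  counts <- rep(base, k)
  if (extra > 0) {
    idx <- if (from_end) seq(k, by = -1, length.out = extra)
           else seq_len(extra)
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

#' Stratified ground-truth sample
#'
#' Draws reference points of known class for map accuracy assessment:
#' `n_cliff` points on true-cliff cells and `n_noncliff` on true non-cliff
#' cells, allocated across strata (survey squares) as evenly as possible
#' (per-stratum totals differ by at most 1), sampled uniformly without
#' replacement within each stratum, deterministically for a given seed.
#' The field protocol this reproduces used 100 points (50 + 50) over seven
#' 10x10-km squares, i.e. 14-15 points per square.
#'
#' @param truth_mask an [elev_grid()] (or logical matrix) marking true
#'   cliff cells.
#' @param n_cliff,n_noncliff number of points of each class.
#' @param strata list of region masks (same geometry), one per survey
#'   square; `NULL` treats the whole grid as one stratum.
#' @param region_mask optional mask restricting all sampling (e.g. the
#'   remotely surveyed area); `NULL` means no restriction.
#' @param seed integer RNG seed.
#' @param strict when `TRUE` (default) a stratum without enough candidate
#'   cells of a class is an error; when `FALSE` the shortfall is
#'   reallocated to strata with spare capacity (an error only if the whole
#'   region cannot supply the points).
#' @return Data frame with columns `x`, `y`, `true_class`, `stratum`.
#' @export
sample_ground_truth <- function(truth_mask, n_cliff, n_noncliff,
                                strata = NULL, region_mask = NULL,
                                seed = 1L, strict = TRUE) {
  grid <- truth_mask
  if (!inherits(grid, "elev_grid"))
    stop_invalid("`truth_mask` must be an elev_grid")
  truth <- !is.na(grid$values) & grid$values != 0
  valid <- !is.na(grid$values)
  if (!is.null(region_mask)) {
    rm_ <- if (inherits(region_mask, "elev_grid")) {
      !is.na(region_mask$values) & region_mask$values != 0
    } else region_mask != 0
    valid <- valid & rm_
  }
  if (is.null(strata))
    strata <- list(matrix(TRUE, nrow(grid$values), ncol(grid$values)))
  strata <- lapply(strata, function(s) {
    if (inherits(s, "elev_grid")) s$values != 0 else s != 0
  })
  k <- length(strata)
  alloc_cliff <- apportion(n_cliff, k, from_end = FALSE)
  alloc_non <- apportion(n_noncliff, k, from_end = TRUE)
  cap_cliff <- vapply(strata, function(s)
    sum(s & valid & truth), numeric(1))
  cap_non <- vapply(strata, function(s)
    sum(s & valid & !truth), numeric(1))
  if (strict) {
    bad <- which(cap_cliff < alloc_cliff)
    if (length(bad))
      stop_invalid("stratum %d has %d cliff cells, needs %d",
                   bad[1], cap_cliff[bad[1]], alloc_cliff[bad[1]])
    bad <- which(cap_non < alloc_non)
    if (length(bad))
      stop_invalid("stratum %d has %d non-cliff cells, needs %d",
                   bad[1], cap_non[bad[1]], alloc_non[bad[1]])
  } else {
    alloc_cliff <- redistribute(alloc_cliff, cap_cliff, "cliff")
    alloc_non <- redistribute(alloc_non, cap_non, "non-cliff")
  }
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(k)) {
      in_s <- strata[[s]] & valid
      cand_cliff <- which(in_s & truth)
      cand_non <- which(in_s & !truth)
      pick <- c(sample_int(cand_cliff, alloc_cliff[s]),
                sample_int(cand_non, alloc_non[s]))
      cls <- rep(c("cliff", "non-cliff"), c(alloc_cliff[s], alloc_non[s]))
      if (length(pick)) {
        rc <- arrayInd(pick, dim(grid$values))
        rows[[s]] <- data.frame(
          x = grid$xll + (rc[, 2] - 0.5) * grid$cell_size,
          y = grid$yll + (nrow(grid$values) - rc[, 1] + 0.5) *
            grid$cell_size,
          true_class = cls, stratum = s)
      }
    }
    do.call(rbind, rows)
  })
}

# cap allocations at per-stratum capacity, pushing the shortfall onto
# strata with spare cells (round-robin); errors if total capacity is short
redistribute <- function(alloc, cap, what) {
  if (sum(cap) < sum(alloc))
    stop_invalid("region has %d %s cells for %d points",
                 sum(cap), what, sum(alloc))
  short <- sum(pmax(alloc - cap, 0))
  alloc <- pmin(alloc, cap)
  while (short > 0) {
    open <- which(alloc < cap)
    take <- open[seq_len(min(short, length(open)))]
    alloc[take] <- alloc[take] + 1L
    short <- short - length(take)
  }
  alloc
}

# sample() without the length-1 surprise
sample_int <- function(pool, n) {
  if (n == 0L) return(integer(0))
  if (length(pool) == 1L) return(rep(pool, n))
  sample(pool, n)
}

#' Accuracy report for several cliff maps
#'
#' Computes the full metric set for each map against the same reference
#' points, in the layout of a published accuracy table (methods as
#' columns).
#'
#' @param maps named list of 0/1 cliff [elev_grid()]s.
#' @param points ground-truth points from [sample_ground_truth()].
#' @param convention convention for user's accuracy / commission error,
#'   see [accuracy_metrics].
#' @return Data frame with one row per metric and one column per map.
#' @export
accuracy_report <- function(maps, points,
                            convention = c("reference", "map")) {
  convention <- match.arg(convention)
  cols <- lapply(maps, function(m) {
    cm <- evaluate_map(m, points)
    c(cliff_correct = cm$tp, cliff_incorrect = cm$fn,
      noncliff_correct = cm$tn, noncliff_incorrect = cm$fp,
      overall_accuracy = overall_accuracy(cm),
      producers_accuracy = producers_accuracy(cm, "cliff"),
      users_accuracy = users_accuracy(cm, "cliff", convention),
      omission_error_rate = omission_error_rate(cm),
      commission_error_rate = commission_error_rate(cm, convention),
      cohens_kappa = cohens_kappa(cm))
  })
  out <- data.frame(metric = names(cols[[1]]))
  for (nm in names(maps)) out[[nm]] <- unname(cols[[nm]])
  out
}
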