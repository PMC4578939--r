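# 2-D free-energy contour maps over order-parameter pairs, intermediate
# ensemble extraction, minimax basin barriers, and melting curves.
#
# Delta A(i) = -RT ln(p_i / p_ref) with the reference cell chosen as the
# highest-probability cell; R = 8.314e-3 kJ/(mol K). Unoccupied cells carry
# an explicit +Inf, never a sentinel number.

#' Gas constant in kJ/(mol K)
#' @export
GAS_CONSTANT_KJ <- 8.314e-3

#' Build a 2-D free-energy map from two order-parameter series
#'
#' The (x, y) points are histogrammed on an `n_bins` x `n_bins` grid
#' (default 20 x 20). Cell probabilities are counts / total and the free
#' energy of cell i is -RT ln(p_i / p_ref) where ref is the
#' maximum-probability cell (ties broken lexicographically).
#'
#' @param x,y numeric series of equal length (one value per frame).
#' @param temperature temperature in K.
#' @param n_bins grid size per axis (default 20).
#' @param ranges optional list(x = c(min, max), y = c(min, max)); default the
#'   data range, with points at the max edge assigned to the last bin.
#' @param axis_names character(2) axis labels.
#' @return object of class `FreeEnergyMap`: list with `counts`,
#'   `probability`, `delta_a` (all n_bins x n_bins; `delta_a` is +Inf on
#'   unoccupied cells), `axis_x`, `axis_y` (name, breaks), `temperature`,
#'   `reference_cell` (row, col).
#' @export
build_map <- function(x, y, temperature, n_bins = 20, ranges = NULL,
                      axis_names = c("x", "y")) {
  if (length(x) == 0 || length(x) != length(y)) {
    stop("x and y must be non-empty series of equal length")
  }
  stopifnot(temperature > 0, n_bins >= 1)
  rng <- list(x = if (is.null(ranges$x)) range(x) else ranges$x,
              y = if (is.null(ranges$y)) range(y) else ranges$y)
  bx <- seq(rng$x[1], rng$x[2], length.out = n_bins + 1)
  by <- seq(rng$y[1], rng$y[2], length.out = n_bins + 1)
  ix <- bin_index(x, bx)
  iy <- bin_index(y, by)
  keep <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0L, n_bins, n_bins)
  if (any(keep)) {
    tab <- table(factor(ix[keep], levels = seq_len(n_bins)),
                 factor(iy[keep], levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), n_bins, n_bins)
  }
  prob <- counts / sum(counts)
  ref <- select_reference_cell(counts)
  delta_a <- matrix(Inf, n_bins, n_bins)
  occ <- counts > 0
  delta_a[occ] <- -GAS_CONSTANT_KJ * temperature *
    log(prob[occ] / prob[ref[1], ref[2]])
  structure(list(counts = counts, probability = prob, delta_a = delta_a,
                 axis_x = list(name = axis_names[1], breaks = bx),
                 axis_y = list(name = axis_names[2], breaks = by),
                 temperature = temperature, reference_cell = ref),
            class = "FreeEnergyMap")
}

# Bin index with the max edge folded into the last bin; NA outside range.
#' @keywords internal
bin_index <- function(v, breaks) {
  n <- length(breaks) - 1
  i <- findInterval(v, breaks, rightmost.closed = TRUE)
  i[v < breaks[1] | v > breaks[n + 1]] <- NA
  i
}

#' @export
print.FreeEnergyMap <- function(x, ...) {
  cat(sprintf("FreeEnergyMap %dx%d (%s vs %s), T = %g K, ref cell (%d, %d), %d points\n",
              nrow(x$counts), ncol(x$counts), x$axis_x$name, x$axis_y$name,
              x$temperature, x$reference_cell[1], x$reference_cell[2],
              sum(x$counts)))
  invisible(x)
}

#' Reference (maximum probability) cell of a count grid
#'
#' Ties are broken toward the smallest (row, col) in lexicographic order.
#'
#' @param counts integer matrix of cell counts.
#' @return integer vector c(row, col).
#' @export
select_reference_cell <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0) stop("no occupied cells")
  best <- max(counts)
  hits <- which(counts == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  as.integer(hits[1, ])
}

#' Extract the frames inside an order-parameter window
#'
#' Both window bounds are inclusive. An empty selection is valid.
#'
#' @param x,y order-parameter series.
#' @param window_x,window_y numeric c(min, max).
#' @param label optional source label.
#' @return object of class `EnsembleSelection`: list with `frame_indices`,
#'   `window_x`, `window_y`, `label`.
#' @export
extract_ensemble <- function(x, y, window_x, window_y, label = "") {
  stopifnot(window_x[1] <= window_x[2], window_y[1] <= window_y[2])
  idx <- which(x >= window_x[1] & x <= window_x[2] &
                 y >= window_y[1] & y <= window_y[2])
  structure(list(frame_indices = idx, window_x = window_x,
                 window_y = window_y, label = label),
            class = "EnsembleSelection")
}

#' Minimax free-energy barrier between two cells of a map
#'
#' Over all 8-connected grid paths between `cell_a` and `cell_b` passing
#' only through occupied cells, the minimum of the path maximum of Delta A,
#' minus Delta A(cell_a). +Inf when unreachable.
#'
#' @param map a `FreeEnergyMap`.
#' @param cell_a,cell_b integer c(row, col); both must be occupied.
#' @return barrier in kJ/mol.
#' @export
basin_barrier <- function(map, cell_a, cell_b) {
  da <- map$delta_a
  if (!is.finite(da[cell_a[1], cell_a[2]]) || !is.finite(da[cell_b[1], cell_b[2]])) {
    stop("both endpoint cells must be occupied")
  }
  if (all(cell_a == cell_b)) return(0)
  # grow connectivity by increasing Delta A threshold (levels of occupied cells)
  levels <- sort(unique(da[is.finite(da)]))
  levels <- levels[levels >= max(da[cell_a[1], cell_a[2]], da[cell_b[1], cell_b[2]])]
  for (lev in levels) {
    if (cells_connected(da <= lev, cell_a, cell_b)) {
      return(lev - da[cell_a[1], cell_a[2]])
    }
  }
  Inf
}

# BFS connectivity on a logical grid with 8-connectivity.
#' @keywords internal
cells_connected <- function(open, a, b) {
  if (!open[a[1], a[2]] || !open[b[1], b[2]]) return(FALSE)
  nr <- nrow(open); nc <- ncol(open)
  visited <- matrix(FALSE, nr, nc)
  queue <- list(a)
  visited[a[1], a[2]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (all(cur == b)) return(TRUE)
    for (dr in -1:1) for (dc in -1:1) {
      r <- cur[1] + dr; cc <- cur[2] + dc
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
          !visited[r, cc] && open[r, cc]) {
        visited[r, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(r, cc)
      }
    }
  }
  FALSE
}

#' Free-energy gap between two basins from window populations
#'
#' Frames are assigned to each basin by inclusive order-parameter windows;
#' the gap is -RT ln(n_b / n_a). This aggregates a basin spread over
#' several grid cells into one population, so the estimate is exactly
#' binomial in the frame counts.
#'
#' @param x,y order-parameter series.
#' @param window_a,window_b lists with elements `x` and `y`, each c(min, max).
#' @param temperature temperature in K.
#' @return Delta A (kJ/mol), positive when basin b is less populated.
#' @export
basin_delta_a <- function(x, y, window_a, window_b, temperature) {
  na <- length(extract_ensemble(x, y, window_a$x, window_a$y)$frame_indices)
  nb <- length(extract_ensemble(x, y, window_b$x, window_b$y)$frame_indices)
  if (na == 0 || nb == 0) stop("a basin window contains no frames")
  -GAS_CONSTANT_KJ * temperature * log(nb / na)
}

#' Melting curve: fraction of unfolded frames per temperature
#'
#' A frame is unfolded when its RMSD lies inside the unfolded window
#' (default 0.3-0.9 nm, inclusive).
#'
#' @param rmsd_by_temperature named list of RMSD series (nm); names are
#'   temperatures in K.
#' @param unfolded_window numeric c(min, max) in nm.
#' @return object of class `MeltingCurve`: data.frame with `temperature_K`,
#'   `fraction_unfolded`, plus attribute `unfolded_window`.
#' @export
melting_curve <- function(rmsd_by_temperature, unfolded_window = c(0.3, 0.9)) {
  if (length(rmsd_by_temperature) < 2) stop("need at least 2 temperatures")
  temps <- as.numeric(names(rmsd_by_temperature))
  if (anyNA(temps)) stop("list names must be temperatures in K")
  ord <- order(temps)
  frac <- vapply(rmsd_by_temperature, function(r) {
    if (length(r) == 0) stop("a temperature has zero frames")
    mean(r >= unfolded_window[1] & r <= unfolded_window[2])
  }, numeric(1))
  out <- data.frame(temperature_K = temps[ord], fraction_unfolded = frac[ord])
  attr(out, "unfolded_window") <- unfolded_window
  class(out) <- c("MeltingCurve", "data.frame")
  out
}

#' Melting temperature from a logistic fit
#'
#' The fraction-unfolded curve is min-max normalized to \[0, 1\] and fitted
#' with a two-parameter logistic f(T) = 1 / (1 + exp(-(T - Tm) / s)) by
#' least squares; the midpoint Tm is returned.
#'
#' @param curve a `MeltingCurve` (or data.frame with `temperature_K`,
#'   `fraction_unfolded`).
#' @return Tm in K.
#' @export
fit_tm <- function(curve) {
  tt <- curve$temperature_K
  f <- curve$fraction_unfolded
  if (diff(range(f)) < 1e-12) stop("melting curve is flat: no transition to fit")
  fn <- (f - min(f)) / (max(f) - min(f))
  if (max(fn) < 0.5 || min(fn) > 0.5) {
    stop("normalized curve does not cross 0.5: midpoint undefined")
  }
  # rough midpoint for the start value: first crossing of 0.5
  i <- which(fn >= 0.5)[1]
  tm0 <- if (i == 1) tt[1] else {
    tt[i - 1] + (0.5 - fn[i - 1]) * (tt[i] - tt[i - 1]) / (fn[i] - fn[i - 1])
  }
  s0 <- max(diff(range(tt)) / 20, 1e-6)
  fit <- stats::nls(fn ~ 1 / (1 + exp(-(tt - tm) / s)),
                    start = list(tm = tm0, s = s0),
                    control = stats::nls.control(warnOnly = TRUE))
  tm <- stats::coef(fit)[["tm"]]
  if (tm < min(tt) || tm > max(tt)) stop("fitted midpoint outside data range")
  tm
}

#' Write a FreeEnergyMap as TSV matrix plus JSON metadata
#'
#' @param map a `FreeEnergyMap`.
#' @param prefix output path prefix; writes `<prefix>_delta_a.tsv`,
#'   `<prefix>_counts.tsv`, `<prefix>_meta.json`.
#' @return character vector of the files written, invisibly.
#' @export
write_map <- function(map, prefix) {
  da <- map$delta_a
  da[!is.finite(da)] <- NA   # TSV carries NA for unoccupied, Inf stays in R
  f1 <- paste0(prefix, "_delta_a.tsv")
  f2 <- paste0(prefix, "_counts.tsv")
  f3 <- paste0(prefix, "_meta.json")
  utils::write.table(da, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(map$counts, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(axis_x = map$axis_x, axis_y = map$axis_y,
                            temperature = map$temperature,
                            reference_cell = map$reference_cell),
                       f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}
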