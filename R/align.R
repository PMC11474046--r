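#' Align a growth-rate series on cell-cycle units
#'
#' Maps each inter-frame growth-rate step to normalized cell-cycle time
#' (0 at birth, 1 at division) using the step's midpoint time, then averages
#' the rates within `n_bins` equal-width bins. Steps whose midpoints fall
#' outside the birth-division interval are dropped; empty bins are `NA`.
#' The mapping is scale-free: multiplying all times by a constant leaves the
#' binned vector unchanged.
#'
#' @param inst_rate Growth-rate steps (min^-1), one per consecutive frame pair.
#' @param times Frame times (min), length `length(inst_rate) + 1`.
#' @param birth_time,division_time Cycle endpoints (min), `birth < division`.
#' @param n_bins Number of equal-width cell-cycle-unit bins.
#' @return List with `bin_centers` (length `n_bins`) and `rate` (per-bin mean,
#'   `NA` where no step contributed).
#' @export
align_cell_cycle <- function(inst_rate, times, birth_time, division_time,
                             n_bins = 30L) {
  if (length(times) != length(inst_rate) + 1L)
    stopf("times must have one more element than inst_rate")
  if (!(birth_time < division_time)) stopf("zero- or negative-length cell cycle")
  t_mid <- (times[-1L] + times[-length(times)]) / 2
  cc <- (t_mid - birth_time) / (division_time - birth_time)
  keep <- cc >= 0 & cc <= 1 & !is.na(inst_rate)
  cc <- cc[keep]; r <- inst_rate[keep]
  idx <- pmin(pmax(ceiling(cc * n_bins), 1L), n_bins)
  rate <- rep(NA_real_, n_bins)
  if (length(idx)) {
    agg <- vapply(split(r, idx), mean, numeric(1))
    rate[as.integer(names(agg))] <- agg
  }
  list(bin_centers = (seq_len(n_bins) - 0.5) / n_bins, rate = rate)
}

#' Population mean growth-rate curve with bootstrap confidence band
#'
#' Per-bin mean over cells of cell-cycle-aligned growth-rate vectors, with a
#' percentile bootstrap confidence band obtained by resampling cells (never
#' individual bins). Bins to which fewer than two cells contribute have their
#' confidence limits set to `NA`. Deterministic under a fixed `seed`.
#'
#' @param aligned List of per-cell aligned rate vectors (equal length,
#'   `NA` for empty bins), or a cells x bins matrix.
#' @param n_boot Number of bootstrap resamples of the cell set.
#' @param alpha Two-sided miscoverage for the percentile band.
#' @param seed Integer seed.
#' @param bin_centers Optional bin centers; defaults to midpoints of
#'   equal-width bins.
#' @return An `aligned_population` object: `bin_centers`, `mean_rate`,
#'   `ci_low`, `ci_high`, `n_contrib` (cells per bin), `n_cells`.
#' @export
population_mean_curve <- function(aligned, n_boot = 1000L, alpha = 0.05,
                                  seed = 1L, bin_centers = NULL) {
  mat <- if (is.matrix(aligned)) aligned
         else do.call(rbind, lapply(aligned, function(a)
           if (is.list(a)) a$rate else a))
  if (is.null(mat) || nrow(mat) < 2L) stopf("need at least 2 cells")
  n_cells <- nrow(mat); n_bins <- ncol(mat)
  n_contrib <- colSums(!is.na(mat))
  mean_rate <- ifelse(n_contrib > 0, colMeans(mat, na.rm = TRUE), NA_real_)
  boot <- with_seed(seed, {
    res <- matrix(NA_real_, n_boot, n_bins)
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n_cells, n_cells, replace = TRUE)
      res[b, ] <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    }
    res
  })
  qs <- apply(boot, 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
  ci_low <- qs[1L, ]; ci_high <- qs[2L, ]
  ci_low[n_contrib < 2L] <- NA_real_
  ci_high[n_contrib < 2L] <- NA_real_
  boot_se <- apply(boot, 2L, stats::sd, na.rm = TRUE)
  structure(list(
    bin_centers = bin_centers %||% ((seq_len(n_bins) - 0.5) / n_bins),
    mean_rate = mean_rate, ci_low = ci_low, ci_high = ci_high,
    boot_se = boot_se, n_contrib = n_contrib, n_cells = n_cells,
    alpha = alpha
  ), class = "aligned_population")
}

#' @export
print.aligned_population <- function(x, ...) {
  cat(sprintf("Aligned population curve: %d cells, %d cell-cycle bins\n",
              x$n_cells, length(x$bin_centers)))
  rng <- range(x$mean_rate, na.rm = TRUE)
  cat(sprintf("  mean rate range: %.5f to %.5f min^-1 (%.0f%% band)\n",
              rng[1], rng[2], 100 * (1 - x$alpha)))
  invisible(x)
}

#' Tempogram matrix
#'
#' One row per cell showing its aligned growth-rate vector, with rows sorted
#' by interdivision time ascending (shortest cycle in the first row).
#'
#' @param aligned List of per-cell aligned rate vectors (or matrix).
#' @param interdivision_times Numeric vector, one per cell.
#' @return Matrix (cells x bins) with `interdivision_time` row attribute,
#'   class `tempogram`.
#' @export
tempogram <- function(aligned, interdivision_times) {
  mat <- if (is.matrix(aligned)) aligned
         else do.call(rbind, lapply(aligned, function(a)
           if (is.list(a)) a$rate else a))
  if (nrow(mat) != length(interdivision_times))
    stopf("one interdivision time per cell required")
  ord <- order(interdivision_times)
  out <- mat[ord, , drop = FALSE]
  attr(out, "interdivision_time") <- interdivision_times[ord]
  class(out) <- c("tempogram", class(out))
  out
}

#' Bin cells by G1 duration
#'
#' Assigns each cell to the interval containing its G1 duration. Intervals
#' are lower-inclusive and upper-exclusive, except the interval with the
#' largest upper edge, which is closed at the top. Cells falling in no
#' interval are excluded with a logged reason.
#'
#' @param g1 Numeric G1 durations (min), optionally named by cell id.
#' @param edges List of `c(lo, hi)` interval pairs, non-overlapping.
#' @return List with `groups` (list of index vectors per interval),
#'   `excluded` (indices) and `excluded_reason`.
#' @export
bin_by_g1 <- function(g1, edges) {
  if (!length(edges)) stopf("need at least one interval")
  em <- do.call(rbind, lapply(edges, function(e) {
    if (length(e) != 2L || e[1] >= e[2]) stopf("each edge must be c(lo, hi) with lo < hi")
    as.numeric(e)
  }))
  ord <- order(em[, 1L])
  if (nrow(em) > 1L && any(em[ord, 2L][-nrow(em)] > em[ord, 1L][-1L]))
    stopf("overlapping intervals")
  top <- which.max(em[, 2L])
  n <- length(g1)
  assign <- rep(NA_integer_, n)
  for (j in seq_len(nrow(em))) {
    inside <- g1 >= em[j, 1L] &
      (if (j == top) g1 <= em[j, 2L] else g1 < em[j, 2L])
    inside[is.na(inside)] <- FALSE
    assign[inside & is.na(assign)] <- j
  }
  ids <- names(g1) %||% as.character(seq_len(n))
  groups <- lapply(seq_len(nrow(em)), function(j) which(assign == j))
  excl <- which(is.na(assign) & !is.na(g1))
  excl_na <- which(is.na(g1))
  list(groups = groups,
       edges = em,
       excluded = c(excl, excl_na),
       excluded_reason = c(
         stats::setNames(rep("outside all intervals", length(excl)), ids[excl]),
         stats::setNames(rep("G1 duration undefined", length(excl_na)), ids[excl_na])))
}

#' Tertile interval edges for G1 binning
#'
#' Convenience for the three-group binning used when comparing growth curves
#' across short/intermediate/long G1 cells: interval edges at the empirical
#' tertiles of the observed G1 durations.
#'
#' @param g1 Numeric G1 durations.
#' @return List of three `c(lo, hi)` pairs covering the observed range.
#' @export
g1_tertile_edges <- function(g1) {
  g1 <- g1[!is.na(g1)]
  qs <- stats::quantile(g1, c(1, 2) / 3, names = FALSE, type = 7)
  list(c(min(g1), qs[1]), c(qs[1], qs[2]), c(qs[2], max(g1)))
}
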