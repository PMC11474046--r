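#' Detect diffraction-limited fluorescent foci within cell masks
#'
#' Band-pass spot detection: the image is filtered with a
#' difference-of-Gaussians at the point-spread-function scale
#' (`sigma = psf_sigma` minus `sigma = 2 * psf_sigma`), local maxima of the
#' response are kept when they exceed the cell's robust threshold
#' (median + `snr_threshold` x MAD of the response within the cell mask) and
#' their raw peak intensity clears the cell background by `snr_threshold`
#' photon-noise standard deviations (which rejects the band-pass ridge a
#' rod-shaped mask produces at its ends), and maxima of the same cell closer
#' than `min_separation` pixels are merged
#' keeping the brighter one. Focus brightness is the integrated image
#' intensity in a small disc minus the local (cell-median) background, and
#' each focus also carries its coordinate along the cell's long axis
#' (0 and 1 at the poles), obtained from the principal axis of the mask.
#'
#' @param fluor Numeric matrix (fluorescence image, rows = y).
#' @param mask Integer matrix of the same shape; positive cell labels,
#'   background 0.
#' @param psf_sigma PSF standard deviation in pixels.
#' @param min_separation Merge radius in pixels.
#' @param snr_threshold Robust threshold multiplier.
#' @return `data.frame` with one row per focus: `cell_id`, `x_px`, `y_px`
#'   (1-based pixel centers), `axis_coord`, `brightness`, `response`.
#' @export
detect_foci <- function(fluor, mask, psf_sigma = 1.3, min_separation = 3,
                        snr_threshold = 5) {
  if (!all(dim(fluor) == dim(mask))) stopf("image and mask shapes differ")
  empty <- data.frame(cell_id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      axis_coord = numeric(0), brightness = numeric(0),
                      response = numeric(0))
  labels <- sort(unique(mask[mask > 0]))
  if (!length(labels)) return(empty)
  img <- matrix(as.numeric(fluor), nrow(fluor))
  dog <- EBImage::gblur(img, sigma = psf_sigma) -
         EBImage::gblur(img, sigma = 2 * psf_sigma)
  locmax <- local_maxima(dog)
  out <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    L <- labels[k]
    inL <- mask == L
    vals <- dog[inL]
    thr <- stats::median(vals) + snr_threshold * stats::mad(vals)
    cellbg0 <- stats::median(img[inL])
    # photon-noise floor on the raw peak height rejects the band-pass ridge
    # artifacts a rod-shaped mask produces at its ends
    peak_floor <- cellbg0 + snr_threshold * sqrt(max(cellbg0, 1))
    cand <- which(locmax & inL & dog > thr & img > peak_floor, arr.ind = TRUE)
    if (!nrow(cand)) next
    resp <- dog[cand]
    keep <- merge_close_peaks(cand, resp, min_separation)
    cand <- cand[keep, , drop = FALSE]; resp <- resp[keep]
    ax <- mask_axis(inL)
    cellbg <- cellbg0
    rad <- max(2L, ceiling(2 * psf_sigma))
    rows <- lapply(seq_len(nrow(cand)), function(j) {
      r <- cand[j, 1L]; c <- cand[j, 2L]
      br <- disc_intensity(img, r, c, rad) - cellbg * disc_size(rad)
      data.frame(cell_id = L, x_px = c, y_px = r,
                 axis_coord = axis_position(ax, r, c),
                 brightness = br, response = resp[j])
    })
    out[[k]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Strict-or-equal local maxima over the 8-neighborhood (interior pixels only).
local_maxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  res <- matrix(FALSE, nr, nc)
  if (nr < 3L || nc < 3L) return(res)
  ci <- 2:(nr - 1L); cj <- 2:(nc - 1L)
  ctr <- x[ci, cj]
  # strict against lexicographically earlier neighbours, >= against later
  # ones, so a flat plateau yields exactly one maximum
  ok <- ctr > x[ci - 1L, cj] & ctr > x[ci, cj - 1L] &
        ctr > x[ci - 1L, cj - 1L] & ctr > x[ci + 1L, cj - 1L] &
        ctr >= x[ci + 1L, cj] & ctr >= x[ci, cj + 1L] &
        ctr >= x[ci - 1L, cj + 1L] & ctr >= x[ci + 1L, cj + 1L]
  res[ci, cj] <- ok
  res
}

# Greedy proximity merge: visit peaks by decreasing response, drop any peak
# within `min_sep` of an already-kept one.
merge_close_peaks <- function(coords, resp, min_sep) {
  ord <- order(resp, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all((coords[kept, 1L] - coords[i, 1L])^2 +
            (coords[kept, 2L] - coords[i, 2L])^2 >= min_sep^2))
      kept <- c(kept, i)
  }
  sort(kept)
}

disc_size <- function(rad) {
  g <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  sum(g$dr^2 + g$dc^2 <= rad^2)
}

disc_intensity <- function(img, r, c, rad) {
  g <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  g <- g[g$dr^2 + g$dc^2 <= rad^2, ]
  rr <- pmin(pmax(r + g$dr, 1L), nrow(img))
  cc <- pmin(pmax(c + g$dc, 1L), ncol(img))
  sum(img[cbind(rr, cc)])
}

# Principal axis of a logical mask: center, unit direction, half-extents.
mask_axis <- function(inL) {
  px <- which(inL, arr.ind = TRUE)
  ctr <- colMeans(px)
  if (nrow(px) < 2L)
    return(list(ctr = ctr, dir = c(0, 1), lo = 0, hi = 0))
  cv <- stats::cov(px)
  e <- eigen(cv, symmetric = TRUE)
  dir <- e$vectors[, 1L]
  proj <- (px[, 1L] - ctr[1L]) * dir[1L] + (px[, 2L] - ctr[2L]) * dir[2L]
  list(ctr = ctr, dir = dir, lo = min(proj), hi = max(proj))
}

axis_position <- function(ax, r, c) {
  if (ax$hi - ax$lo <= 0) return(0.5)
  proj <- (r - ax$ctr[1L]) * ax$dir[1L] + (c - ax$ctr[2L]) * ax$dir[2L]
  min(1, max(0, (proj - ax$lo) / (ax$hi - ax$lo)))
}

#' G1 duration from focus counts
#'
#' The G1 phase ends at the first fluorescence frame, at or after birth, with
#' at least two foci; the duration is that frame's time minus the birth time.
#' When the first observed frame at or after birth already shows two foci the
#' cell has no observed single-focus period and the duration is 0 (the "no G1
#' phase" category). If two foci are never seen before the end of the track
#' the duration is undefined (`NA`) and the result is flagged.
#'
#' @param times Fluorescence frame times (min), increasing.
#' @param counts Focus counts per frame.
#' @param birth_time Birth time (min) under the active birth definition.
#' @return List: `g1_end_time`, `g1_duration` (`NA` when undefined),
#'   `censored` (`TRUE` when two foci were never observed).
#' @export
g1_from_foci <- function(times, counts, birth_time) {
  if (length(times) != length(counts)) stopf("times and counts lengths differ")
  at_or_after <- which(times >= birth_time - 1e-9)
  if (!length(at_or_after))
    return(list(g1_end_time = NA_real_, g1_duration = NA_real_, censored = TRUE))
  idx <- at_or_after[counts[at_or_after] >= 2L]
  if (!length(idx))
    return(list(g1_end_time = NA_real_, g1_duration = NA_real_, censored = TRUE))
  first2 <- idx[1L]
  dur <- if (first2 == at_or_after[1L]) 0 else times[first2] - birth_time
  list(g1_end_time = times[first2], g1_duration = dur, censored = FALSE)
}

#' Unipolar/bipolar localization of polar markers
#'
#' Classifies a cell's foci by their position along the long axis: foci
#' within `pole_fraction` of either pole are polar; the pattern is bipolar if
#' both poles are occupied, unipolar if exactly one is, and `"other"`
#' otherwise (including cells without foci).
#'
#' @param axis_coords Focus coordinates along the cell axis, in `[0, 1]`.
#' @param pole_fraction Fraction of the axis counted as polar at each end.
#' @return `"unipolar"`, `"bipolar"` or `"other"`.
#' @export
classify_polarity <- function(axis_coords, pole_fraction = 0.2) {
  if (!length(axis_coords)) return("other")
  pole1 <- any(axis_coords < pole_fraction)
  pole2 <- any(axis_coords > 1 - pole_fraction)
  if (pole1 && pole2) "bipolar"
  else if (pole1 || pole2) "unipolar"
  else "other"
}
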