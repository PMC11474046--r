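#' Rendering parameters for synthetic fluorescence frames
#'
#' @param pixel_size Pixel size (um/px).
#' @param psf_sigma Point-spread-function standard deviation (px).
#' @param background_level Camera background (counts).
#' @param cell_level Diffuse cytoplasmic fluorescence added inside cell
#'   masks (counts).
#' @param focus_amplitude Peak amplitude of a rendered focus (counts); the
#'   SNR in the `amplitude / sqrt(background)` sense is
#'   `focus_amplitude / sqrt(background_level + cell_level)`.
#' @param noise_model `"poisson"`, `"gaussian"` or `"none"`.
#' @param noise_sd Gaussian noise sd; defaults to `sqrt(background_level)`.
#' @param cell_width_um Rod width (um) used to draw cell masks.
#' @param image_shape `c(ny, nx)` in px, or `NULL` to fit the cells rendered.
#' @return A `render_params` list.
#' @export
render_params <- function(pixel_size = 0.065, psf_sigma = 1.3,
                          background_level = 100, cell_level = 60,
                          focus_amplitude = 400,
                          noise_model = c("poisson", "gaussian", "none"),
                          noise_sd = NULL, cell_width_um = 0.7,
                          image_shape = NULL) {
  noise_model <- match.arg(noise_model)
  if (psf_sigma <= 0) stopf("psf_sigma must be positive")
  if (focus_amplitude <= 0) stopf("focus_amplitude must be positive")
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_level = background_level, cell_level = cell_level,
                 focus_amplitude = focus_amplitude, noise_model = noise_model,
                 noise_sd = noise_sd %||% sqrt(background_level),
                 cell_width_um = cell_width_um, image_shape = image_shape),
            class = "render_params")
}

um_to_px <- function(u, pixel_size) u / pixel_size + 0.5  # continuous px coord

# Fill a rod (rectangle + semicircular caps) into the label mask.
draw_rod <- function(mask, p1, p2, radius_px, label) {
  u <- p2 - p1
  len <- sqrt(sum(u^2))
  if (len == 0) u <- c(1, 0) else u <- u / len
  # midline endpoints inset by the cap radius
  m1 <- p1 + radius_px * u; m2 <- p2 - radius_px * u
  if (sum((m2 - m1) * u) < 0) { m1 <- m2 <- (p1 + p2) / 2 }
  rr <- max(1, floor(min(p1[2], p2[2]) - radius_px)):min(nrow(mask), ceiling(max(p1[2], p2[2]) + radius_px))
  cc <- max(1, floor(min(p1[1], p2[1]) - radius_px)):min(ncol(mask), ceiling(max(p1[1], p2[1]) + radius_px))
  if (!length(rr) || !length(cc)) return(mask)
  gx <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  gy <- matrix(rr, length(rr), length(cc))
  vx <- m2[1] - m1[1]; vy <- m2[2] - m1[2]
  l2 <- vx^2 + vy^2
  t <- if (l2 == 0) matrix(0, length(rr), length(cc))
       else pmin(1, pmax(0, ((gx - m1[1]) * vx + (gy - m1[2]) * vy) / l2))
  dx <- gx - (m1[1] + t * vx); dy <- gy - (m1[2] + t * vy)
  inside <- dx^2 + dy^2 <= radius_px^2
  sub <- mask[rr, cc]
  sub[inside] <- label
  mask[rr, cc] <- sub
  mask
}

#' Render a synthetic fluorescence frame and label mask
#'
#' Cells are drawn as filled rod shapes (rectangle with semicircular caps)
#' into a uint16-style label mask (positive integer labels, background 0).
#' The fluorescence image is the background level, plus diffuse cytoplasmic
#' signal inside each mask, plus one isotropic Gaussian of sd `psf_sigma` per
#' focus, with Poisson or Gaussian noise applied. A focus outside the image
#' is an error.
#'
#' @param cells `data.frame` with columns `cell_id`, `pole1_x`, `pole1_y`,
#'   `pole2_x`, `pole2_y` (um, world coordinates).
#' @param foci `data.frame` with columns `cell_id`, `x_um`, `y_um` and
#'   optionally `amplitude` (relative, default 1); may be empty or `NULL`.
#' @param render A [render_params()] object.
#' @param seed Integer seed for the noise draw.
#' @return List with `fluor` (numeric matrix) and `mask` (integer matrix),
#'   rows indexing y.
#' @export
render_frame <- function(cells, foci = NULL, render = render_params(),
                         seed = 1L) {
  ps <- render$pixel_size
  shape <- render$image_shape
  if (is.null(shape)) {
    pad <- 10
    nx <- ceiling(max(cells$pole2_x, cells$pole1_x) / ps) + pad
    ny <- ceiling(max(c(cells$pole1_y, cells$pole2_y) + render$cell_width_um) / ps) + pad
    shape <- c(ny, nx)
  }
  mask <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(cells))) {
    p1 <- c(um_to_px(cells$pole1_x[i], ps), um_to_px(cells$pole1_y[i], ps))
    p2 <- c(um_to_px(cells$pole2_x[i], ps), um_to_px(cells$pole2_y[i], ps))
    mask <- draw_rod(mask, p1, p2, radius_px = render$cell_width_um / 2 / ps,
                     label = as.integer(cells$cell_id[i]))
  }
  img <- matrix(render$background_level, shape[1], shape[2])
  img[mask > 0] <- img[mask > 0] + render$cell_level
  if (!is.null(foci) && nrow(foci)) {
    amp <- if ("amplitude" %in% names(foci)) foci$amplitude else rep(1, nrow(foci))
    s <- render$psf_sigma
    for (i in seq_len(nrow(foci))) {
      fx <- um_to_px(foci$x_um[i], ps); fy <- um_to_px(foci$y_um[i], ps)
      if (fx < 1 || fx > shape[2] || fy < 1 || fy > shape[1])
        stopf("focus at (%.1f, %.1f) px lies outside the %d x %d image",
              fx, fy, shape[2], shape[1])
      rr <- max(1, floor(fy - 5 * s)):min(shape[1], ceiling(fy + 5 * s))
      cc <- max(1, floor(fx - 5 * s)):min(shape[2], ceiling(fx + 5 * s))
      gx <- matrix(cc, length(rr), length(cc), byrow = TRUE)
      gy <- matrix(rr, length(rr), length(cc))
      img[rr, cc] <- img[rr, cc] + amp[i] * render$focus_amplitude *
        exp(-((gx - fx)^2 + (gy - fy)^2) / (2 * s^2))
    }
  }
  if (render$noise_model != "none") {
    img <- with_seed(seed, {
      if (render$noise_model == "poisson")
        matrix(stats::rpois(length(img), img), nrow(img))
      else img + matrix(stats::rnorm(length(img), 0, render$noise_sd), nrow(img))
    })
  }
  list(fluor = img, mask = mask)
}

#' Render fluorescence/mask stacks for a lineage simulation
#'
#' Renders every fluorescence frame of a simulation: alive cells are drawn
#' from the tracked table (fluorescence times coincide with even phase
#' frames), and each cell's simulated foci are placed along its midline at
#' their axis coordinates. Returns the ground-truth focus positions in pixel
#' coordinates for round-trip benchmarking of [detect_foci()].
#'
#' @param sim A `lineage_sim`.
#' @param foci_tracks Result of [simulate_foci()].
#' @param render A [render_params()]; `image_shape = NULL` fits the field.
#' @param seed Base seed; frame `i` uses `seed + i`.
#' @return List with `times`, `fluor` (list of matrices), `mask` (list of
#'   integer matrices) and `truth` (data.frame: `time_min`, `cell_id`,
#'   `x_px`, `y_px`, `axis_coord`).
#' @export
render_stacks <- function(sim, foci_tracks, render = render_params(),
                          seed = 1L) {
  p <- sim$params
  ps <- render$pixel_size
  if (is.null(render$image_shape)) {
    pad <- 10
    render$image_shape <- c(
      ceiling((max(sim$table$centroid_y_um) + p$cell_width_um) / ps) + pad,
      ceiling(max(sim$table$pole2_x) / ps) + pad)
  }
  step <- p$frame_interval_fluor / p$frame_interval_phase
  if (abs(step - round(step)) > 1e-9)
    stopf("fluorescence interval must be a multiple of the phase interval for rendering")
  fluor_frames <- sort(unique(sim$table$frame[sim$table$frame %% round(step) == 0]))
  times <- fluor_frames * p$frame_interval_phase
  out_f <- vector("list", length(times)); out_m <- out_f
  truth <- vector("list", length(times))
  for (i in seq_along(times)) {
    rows <- sim$table[sim$table$frame == fluor_frames[i], ]
    fx <- list()
    for (j in seq_len(nrow(rows))) {
      ft <- foci_tracks[[as.character(rows$cell_id[j])]]
      if (is.null(ft)) next
      fr <- ft$foci[abs(ft$foci$time_min - times[i]) < 1e-9, ]
      if (!nrow(fr)) next
      r <- p$cell_width_um / 2
      p1 <- c(rows$pole1_x[j], rows$pole1_y[j])
      p2 <- c(rows$pole2_x[j], rows$pole2_y[j])
      u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
      m1 <- p1 + r * u; m2 <- p2 - r * u
      xy <- t(vapply(fr$axis_coord, function(f) m1 + f * (m2 - m1), numeric(2)))
      fx[[length(fx) + 1L]] <- data.frame(
        cell_id = rows$cell_id[j], x_um = xy[, 1], y_um = xy[, 2],
        amplitude = fr$brightness, axis_coord = fr$axis_coord)
    }
    foci_df <- if (length(fx)) do.call(rbind, fx) else NULL
    fm <- render_frame(rows, foci_df, render, seed = seed + i)
    out_f[[i]] <- fm$fluor; out_m[[i]] <- fm$mask
    truth[[i]] <- if (!is.null(foci_df)) data.frame(
      time_min = times[i], cell_id = foci_df$cell_id,
      x_px = um_to_px(foci_df$x_um, ps), y_px = um_to_px(foci_df$y_um, ps),
      axis_coord = foci_df$axis_coord) else NULL
  }
  list(times = times, fluor = out_f, mask = out_m,
       truth = do.call(rbind, truth), render = render)
}
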