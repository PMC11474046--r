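#' Simulation parameters for synthetic lineages
#'
#' Bundles the generative parameters of the synthetic timelapse: exponential
#' baseline growth with a G1-coupled piecewise-linear growth-rate dip,
#' asymmetric division into a smaller swarmer and a larger stalked daughter,
#' and cytokinesis completing before visible daughter separation.
#'
#' @param baseline_rate Baseline relative growth rate mu0 (min^-1).
#' @param dip_depth Fractional depth d of the G1 growth-rate dip, in `[0, 1)`;
#'   the rate declines linearly from mu0 at birth to `mu0 * (1 - d)` at the
#'   trough.
#' @param recovery_width Duration w (min) of the linear recovery from the
#'   trough back to mu0.
#' @param trough_offset Offset (min) of the trough relative to the end of G1;
#'   0 places the trough exactly at G1 end.
#' @param g1_mean_swarmer,g1_mean_stalked Mean G1 duration (min) by progeny
#'   type, measured from cytokinesis completion.
#' @param g1_dispersion Coefficient of variation of the gamma-distributed G1
#'   durations.
#' @param dip_g1_scale G1 duration (min) at which a cell's dip reaches the
#'   full `dip_depth`; shorter G1 phases dip proportionally less
#'   (`d_cell = dip_depth * min(1, g1 / dip_g1_scale)`), so cells with longer
#'   G1 phases show a more pronounced early-cycle slowdown. Set to 0 to give
#'   every cell the same depth.
#' @param division_ratio Swarmer birth-area fraction s of the mother's
#'   division area, in `(0, 1)`; the stalked daughter receives `1 - s`.
#' @param sep_offset_mean,sep_offset_sd Cytokinesis-to-separation delay (min),
#'   normal truncated at 0.
#' @param frame_interval_phase Phase-contrast imaging interval (min).
#' @param frame_interval_fluor Fluorescence imaging interval (min).
#' @param area_noise_cv Coefficient of variation of the multiplicative
#'   lognormal area measurement noise.
#' @param interdivision_mean,interdivision_sd Interdivision time draw (min),
#'   cytokinesis to cytokinesis.
#' @param founder_area Birth area (um^2) of founder cells.
#' @param cell_width_um Rod width (um) used for synthetic geometry.
#' @param seed Integer seed; fixes every random draw of the simulation.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(baseline_rate = 0.0077,
                       dip_depth = 0.4,
                       recovery_width = 30,
                       trough_offset = 0,
                       g1_mean_swarmer = 40,
                       g1_mean_stalked = 12,
                       g1_dispersion = 0.5,
                       dip_g1_scale = 40,
                       division_ratio = 0.45,
                       sep_offset_mean = 18,
                       sep_offset_sd = 5,
                       frame_interval_phase = 1.5,
                       frame_interval_fluor = 3,
                       area_noise_cv = 0.004,
                       interdivision_mean = 100,
                       interdivision_sd = 15,
                       founder_area = 1.8,
                       cell_width_um = 0.7,
                       seed = 1L) {
  p <- list(baseline_rate = baseline_rate, dip_depth = dip_depth,
            recovery_width = recovery_width, trough_offset = trough_offset,
            g1_mean_swarmer = g1_mean_swarmer, g1_mean_stalked = g1_mean_stalked,
            g1_dispersion = g1_dispersion, dip_g1_scale = dip_g1_scale,
            division_ratio = division_ratio,
            sep_offset_mean = sep_offset_mean, sep_offset_sd = sep_offset_sd,
            frame_interval_phase = frame_interval_phase,
            frame_interval_fluor = frame_interval_fluor,
            area_noise_cv = area_noise_cv,
            interdivision_mean = interdivision_mean,
            interdivision_sd = interdivision_sd,
            founder_area = founder_area, cell_width_um = cell_width_um,
            seed = as.integer(seed))
  if (p$dip_depth < 0 || p$dip_depth >= 1) stopf("dip_depth must be in [0, 1)")
  if (p$division_ratio <= 0 || p$division_ratio >= 1)
    stopf("division_ratio must be in (0, 1)")
  for (f in c("baseline_rate", "frame_interval_phase", "frame_interval_fluor",
              "interdivision_mean", "founder_area", "cell_width_um"))
    if (p[[f]] <= 0) stopf("%s must be positive", f)
  for (f in c("recovery_width", "g1_mean_swarmer", "g1_mean_stalked",
              "g1_dispersion", "dip_g1_scale", "sep_offset_mean",
              "sep_offset_sd", "area_noise_cv", "interdivision_sd"))
    if (p[[f]] < 0) stopf("%s must be non-negative", f)
  structure(p, class = "sim_params")
}

#' G1-coupled growth-rate profile
#'
#' Piecewise-linear relative growth rate as a function of time since birth
#' (cytokinesis completion): the rate declines linearly from `mu0` at `t = 0`
#' to `mu0 * (1 - d)` at the trough (the end of G1 plus `trough_offset`),
#' recovers linearly back to `mu0` over `recovery_width`, and is constant
#' `mu0` thereafter. With `d = 0` or a non-positive trough time, the rate is
#' `mu0` everywhere.
#'
#' @param t Time since birth (min), `>= 0`; vectorized.
#' @param params A [sim_params()] object.
#' @param g1_duration This cell's G1 duration (min).
#' @return Growth rate (min^-1), same length as `t`.
#' @export
growth_rate_profile <- function(t, params, g1_duration) {
  if (any(t < 0)) stopf("t must be non-negative")
  mu0 <- params$baseline_rate; d <- params$dip_depth
  w <- params$recovery_width
  t_tr <- g1_duration + params$trough_offset
  if (d == 0 || t_tr <= 0) return(rep(mu0, length(t)))
  rate <- rep(mu0, length(t))
  in_decline <- t <= t_tr
  rate[in_decline] <- mu0 * (1 - d * t[in_decline] / t_tr)
  if (w > 0) {
    in_rec <- t > t_tr & t <= t_tr + w
    rate[in_rec] <- mu0 * (1 - d * (1 - (t[in_rec] - t_tr) / w))
  }
  rate
}

# Per-cell generative parameters: the dip depth saturates with G1 duration.
cell_dip_params <- function(params, g1_duration) {
  if ((params$dip_g1_scale %||% 0) > 0)
    params$dip_depth <- params$dip_depth * min(1, g1_duration / params$dip_g1_scale)
  params
}

# Closed-form integral of growth_rate_profile from 0 to t (vectorized).
rate_integral <- function(t, params, g1_duration) {
  mu0 <- params$baseline_rate; d <- params$dip_depth
  w <- params$recovery_width
  t_tr <- g1_duration + params$trough_offset
  if (d == 0 || t_tr <= 0) return(mu0 * t)
  out <- numeric(length(t))
  i1 <- mu0 * t_tr * (1 - d / 2)           # integral over the decline
  i2 <- mu0 * w * (1 - d / 2)              # integral over the recovery
  s1 <- t <= t_tr
  out[s1] <- mu0 * (t[s1] - d * t[s1]^2 / (2 * t_tr))
  if (w > 0) {
    s2 <- t > t_tr & t <= t_tr + w
    u <- t[s2] - t_tr
    out[s2] <- i1 + mu0 * (u * (1 - d) + d * u^2 / (2 * w))
  }
  s3 <- t > t_tr + w
  out[s3] <- i1 + i2 + mu0 * (t[s3] - t_tr - w)
  out
}

draw_g1 <- function(type, p) {
  m <- if (type == "swarmer") p$g1_mean_swarmer else p$g1_mean_stalked
  cv <- p$g1_dispersion
  if (m == 0) return(0)
  if (cv == 0) return(m)
  stats::rgamma(1L, shape = 1 / cv^2, scale = m * cv^2)
}

draw_interdivision <- function(p, g1) {
  dt <- if (p$interdivision_sd == 0) p$interdivision_mean
        else stats::rnorm(1L, p$interdivision_mean, p$interdivision_sd)
  max(dt, g1 + 5 * p$frame_interval_phase, 30)
}

draw_sep_offset <- function(p) {
  if (p$sep_offset_sd == 0) return(max(0, p$sep_offset_mean))
  repeat {
    o <- stats::rnorm(1L, p$sep_offset_mean, p$sep_offset_sd)
    if (o >= 0) return(o)
  }
}

# Rod length (pole-to-pole) for a given area: area = w*(L - w) + pi*(w/2)^2.
rod_length <- function(area, width) {
  pmax(width, (area - pi * width^2 / 4) / width + width)
}

#' Simulate an asymmetrically dividing lineage
#'
#' Generates ground-truthed cell lineages: per-cell G1 durations (gamma,
#' type-specific mean), areas integrating the G1-coupled growth-rate profile,
#' asymmetric division (swarmer fraction `division_ratio`), a truncated-normal
#' cytokinesis-to-separation delay, and a tracked-area table sampled on the
#' phase-contrast frame grid with multiplicative lognormal measurement noise.
#' Cell masks split at cytokinesis completion: each daughter's rows start at
#' the first frame at or after its cytokinesis birth, with `cyto_event`
#' flagged there and `sep_event` flagged at the last frame before visible
#' separation. Swarmer daughters move to a new pad position over the three
#' frames following separation; stalked daughters stay put. Deterministic
#' under the seed in `params`.
#'
#' @param params A [sim_params()] object.
#' @param n_generations Number of generations (>= 1); cells of the final
#'   generation are tracked but never divide, so only interior generations
#'   have complete lineages.
#' @param n_founders Number of founder (stalked-type) cells at t = 0.
#' @return A `lineage_sim` object: `params`, `truth` (one row per cell:
#'   ids, types, true birth/division times under both conventions, true G1
#'   duration and birth area), `table` (tracked-area table in the package's
#'   track-table dialect), and `rate_trajectories` (true per-frame rates).
#' @export
simulate_lineage <- function(params, n_generations = 3L, n_founders = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (n_generations < 1L) stopf("n_generations must be >= 1")
  if (n_founders < 1L) stopf("n_founders must be >= 1")
  p <- params
  with_seed(p$seed, {
    cells <- vector("list", 0L)
    slot_pitch <- c(12, 6); slot_ncol <- 8L; slot_margin <- 6
    slot_xy <- function(k) c(slot_margin + (k %% slot_ncol) * slot_pitch[1],
                             slot_margin + (k %/% slot_ncol) * slot_pitch[2])
    next_slot <- 0L
    new_cell <- function(type, mother_id, sister_id, birth_cyto, birth_sep,
                         birth_area, generation, slot, presep_sister) {
      g1 <- draw_g1(type, p)
      dt <- draw_interdivision(p, g1)
      list(cell_id = length(cells) + 1L, progeny_type = type,
           mother_id = mother_id, sister_id = sister_id,
           birth_time_cyto = birth_cyto, birth_time_sep = birth_sep,
           birth_area_true = birth_area, g1_duration_true = g1,
           division_time = birth_cyto + dt, generation = generation,
           slot = slot, presep_sister = presep_sister,
           sep_offset = birth_sep - birth_cyto, next_sep_offset = NA_real_,
           daughter_ids = integer(0))
    }
    for (i in seq_len(n_founders)) {
      cells[[length(cells) + 1L]] <-
        new_cell("stalked", NA_integer_, NA_integer_, 0, 0, p$founder_area,
                 1L, next_slot, NA_integer_)
      next_slot <- next_slot + 1L
    }
    id <- 1L
    while (id <= length(cells)) {
      cell <- cells[[id]]
      if (cell$generation < n_generations) {
        off <- draw_sep_offset(p)
        a_div <- cell$birth_area_true *
          exp(rate_integral(cell$division_time - cell$birth_time_cyto,
                            cell_dip_params(p, cell$g1_duration_true),
                            cell$g1_duration_true))
        id_sw <- length(cells) + 1L; id_st <- id_sw + 1L
        cells[[id_sw]] <- new_cell("swarmer", cell$cell_id, id_st,
                                   cell$division_time, cell$division_time + off,
                                   p$division_ratio * a_div,
                                   cell$generation + 1L, next_slot, id_st)
        next_slot <- next_slot + 1L
        cells[[id_st]] <- new_cell("stalked", cell$cell_id, id_sw,
                                   cell$division_time, cell$division_time + off,
                                   (1 - p$division_ratio) * a_div,
                                   cell$generation + 1L, cell$slot, NA_integer_)
        cells[[id]]$daughter_ids <- c(id_sw, id_st)
        cells[[id]]$next_sep_offset <- off
      }
      id <- id + 1L
    }
    horizon <- max(vapply(cells, `[[`, numeric(1), "division_time"))
    dtp <- p$frame_interval_phase
    sigma <- sqrt(log(1 + p$area_noise_cv^2))
    w <- p$cell_width_um
    rows <- vector("list", length(cells))
    rate_traj <- vector("list", length(cells))
    true_area_at <- function(cell, t_abs) {
      cell$birth_area_true *
        exp(rate_integral(t_abs - cell$birth_time_cyto,
                          cell_dip_params(p, cell$g1_duration_true),
                          cell$g1_duration_true))
    }
    for (cell in cells) {
      f_start <- ceiling(cell$birth_time_cyto / dtp - 1e-9)
      # last frame strictly before this cell's own division (final-generation
      # cells simply end their tracks there with no daughters recorded)
      f_end <- ceiling(cell$division_time / dtp - 1e-9) - 1L
      if (f_end < f_start) f_end <- f_start
      fr <- f_start:f_end
      tt <- fr * dtp
      a_true <- true_area_at(cell, tt)
      a_obs <- if (p$area_noise_cv == 0) a_true
               else a_true * exp(stats::rnorm(length(tt), 0, sigma))
      len <- rod_length(a_true, w)
      # sep_event: last frame strictly before visible separation
      f_sep <- max(f_start, min(f_end, ceiling(cell$birth_time_sep / dtp - 1e-9) - 1L))
      slot_pos <- slot_xy(cell$slot)
      cx <- rep(slot_pos[1], length(fr)); cy <- rep(slot_pos[2], length(fr))
      if (cell$progeny_type == "swarmer" && !is.na(cell$presep_sister)) {
        sis <- cells[[cell$presep_sister]]
        sis_slot <- slot_xy(sis$slot)
        sis_len <- rod_length(true_area_at(sis, tt), w)
        presep_x <- sis_slot[1] + sis_len / 2 + len / 2
        before <- fr <= f_sep
        cx[before] <- presep_x[before]; cy[before] <- sis_slot[2]
        moving <- fr > f_sep & fr <= f_sep + 3L
        frac <- (fr[moving] - f_sep) / 3
        start_x <- if (any(before)) presep_x[sum(before)] else presep_x[1]
        cx[moving] <- start_x + frac * (slot_pos[1] - start_x)
        cy[moving] <- sis_slot[2] + frac * (slot_pos[2] - sis_slot[2])
      }
      rows[[cell$cell_id]] <- data.frame(
        cell_id = cell$cell_id, frame = fr, time_min = tt, area_um2 = a_obs,
        centroid_x_um = cx, centroid_y_um = cy,
        pole1_x = cx - len / 2, pole1_y = cy,
        pole2_x = cx + len / 2, pole2_y = cy,
        mother_id = cell$mother_id, has_stalk = as.integer(cell$progeny_type == "stalked"),
        sep_event = as.integer(fr == f_sep),
        cyto_event = as.integer(fr == f_start))
      rate_traj[[cell$cell_id]] <-
        growth_rate_profile(tt - cell$birth_time_cyto,
                            cell_dip_params(p, cell$g1_duration_true),
                            cell$g1_duration_true)
    }
    truth <- do.call(rbind, lapply(cells, function(cell) data.frame(
      cell_id = cell$cell_id, mother_id = cell$mother_id,
      sister_id = cell$sister_id, generation = cell$generation,
      progeny_type = cell$progeny_type,
      birth_area_true = cell$birth_area_true,
      g1_duration_true = cell$g1_duration_true,
      birth_time_cyto = cell$birth_time_cyto,
      birth_time_sep = cell$birth_time_sep,
      division_time = ifelse(cell$generation < n_generations,
                             cell$division_time, NA_real_),
      sep_offset = cell$sep_offset,
      next_sep_offset = cell$next_sep_offset,
      complete = cell$generation > 1L && cell$generation < n_generations)))
    structure(list(params = p, truth = truth,
                   table = do.call(rbind, rows),
                   rate_trajectories = rate_traj,
                   n_generations = n_generations),
              class = "lineage_sim")
  })
}

#' @export
print.lineage_sim <- function(x, ...) {
  cat(sprintf("Synthetic lineage: %d cells (%d complete), %d tracked frames, %d generations\n",
              nrow(x$truth), sum(x$truth$complete), nrow(x$table),
              x$n_generations))
  invisible(x)
}

#' Simulate a replication-marker focus track for one cell
#'
#' One polar focus at every fluorescence frame before the end of G1, two foci
#' afterwards; the second focus appears one third of the way along the cell's
#' long axis and migrates toward the far pole over 15 min, emulating the
#' rapid segregation of replication origins after initiation. Sampled on the
#' global fluorescence frame grid.
#'
#' @param cell One row of a `lineage_sim` truth table (needs
#'   `birth_time_cyto`, `g1_duration_true`, `division_time`).
#' @param params The [sim_params()] used for the simulation.
#' @param horizon Fallback end time (min) for cells without a division time.
#' @return A `foci_track` list: `cell_id`, `times`, `counts`, and `foci`
#'   (one row per focus: `time_min`, `axis_coord`, `brightness`).
#' @export
simulate_foci_track <- function(cell, params, horizon = NULL) {
  p <- params
  dtf <- p$frame_interval_fluor
  t_end <- cell$division_time
  if (is.na(t_end)) t_end <- horizon %||% (cell$birth_time_cyto + p$interdivision_mean)
  f0 <- ceiling(cell$birth_time_cyto / dtf - 1e-9)
  f1 <- ceiling(t_end / dtf - 1e-9) - 1L
  if (f1 < f0) f1 <- f0
  tt <- (f0:f1) * dtf
  g1_end <- cell$birth_time_cyto + cell$g1_duration_true
  counts <- ifelse(tt < g1_end - 1e-9, 1L, 2L)
  foci <- do.call(rbind, lapply(seq_along(tt), function(i) {
    if (counts[i] == 1L)
      data.frame(time_min = tt[i], axis_coord = 0.08, brightness = 1)
    else {
      mig <- min(1, (tt[i] - g1_end) / 15)
      data.frame(time_min = c(tt[i], tt[i]),
                 axis_coord = c(0.08, 0.33 + 0.59 * mig),
                 brightness = c(1, 1))
    }
  }))
  structure(list(cell_id = cell$cell_id, times = tt, counts = counts,
                 foci = foci, g1_duration_true = cell$g1_duration_true),
            class = "foci_track")
}

#' Simulate focus tracks for every cell of a lineage simulation
#'
#' @param sim A `lineage_sim`.
#' @return Named list of [simulate_foci_track()] results, one per cell.
#' @export
simulate_foci <- function(sim) {
  stopifnot(inherits(sim, "lineage_sim"))
  horizon <- max(sim$table$time_min)
  out <- lapply(seq_len(nrow(sim$truth)), function(i)
    simulate_foci_track(sim$truth[i, ], sim$params, horizon = horizon))
  names(out) <- as.character(sim$truth$cell_id)
  out
}
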