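#' Run the simulation stage
#'
#' Generates a synthetic lineage with the configured parameters, simulates
#' replication-marker focus tracks, and writes the tracked-area table, the
#' ground truth, the per-frame focus counts and a config snapshot into
#' `out_dir`. Optionally renders fluorescence + label-mask TIFF stacks.
#'
#' @param config Pipeline config (see [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param render_images Also write `fluor.tif` / `mask.tif` stacks and the
#'   pixel-space focus truth.
#' @return Invisibly, the `lineage_sim`.
#' @export
run_simulate <- function(config = default_config(), out_dir,
                         render_images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- config_sim_params(config)
  sp$seed <- config$seed
  sim <- simulate_lineage(sp, n_generations = config$sim$n_generations,
                          n_founders = config$sim$n_founders)
  foci <- simulate_foci(sim)
  write_track_table(sim$table, file.path(out_dir, "track_table.csv"))
  utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, na = "")
  counts <- do.call(rbind, lapply(foci, function(ft)
    data.frame(cell_id = ft$cell_id, time_min = ft$times, n_foci = ft$counts)))
  utils::write.csv(counts, file.path(out_dir, "foci_counts.csv"),
                   row.names = FALSE)
  if (render_images) {
    rp <- config_render_params(config)
    st <- render_stacks(sim, foci, rp, seed = config$seed)
    write_tiff_stack(st$fluor, file.path(out_dir, "fluor.tif"))
    write_tiff_stack(st$mask, file.path(out_dir, "mask.tif"))
    utils::write.csv(st$truth, file.path(out_dir, "foci_px_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(page = seq_along(st$times),
                                time_min = st$times),
                     file.path(out_dir, "stack_times.csv"), row.names = FALSE)
  }
  write_config(config, file.path(out_dir, "config_used.yaml"))
  message(sprintf("simulate: %d cells, %d rows, seed %d -> %s",
                  nrow(sim$truth), nrow(sim$table), config$seed, out_dir))
  invisible(sim)
}

#' Run focus detection on TIFF stacks
#'
#' @param config Pipeline config.
#' @param fluor_path,mask_path TIFF stacks (same number of pages).
#' @param out_dir Output directory for `foci.csv` and `foci_counts.csv`.
#' @param times Optional per-page acquisition times (min); defaults to the
#'   page index times the fluorescence interval.
#' @return Invisibly, the detected foci `data.frame`.
#' @export
run_detect_foci <- function(config = default_config(), fluor_path, mask_path,
                            out_dir, times = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fl <- read_tiff_stack(fluor_path)
  mk <- read_tiff_stack(mask_path)
  if (length(fl) != length(mk)) stopf("fluorescence and mask stacks differ in length")
  det <- config$detection
  if (is.null(times)) times <- (seq_along(fl) - 1L) * config$sim$frame_interval_fluor
  out <- vector("list", length(fl))
  for (i in seq_along(fl)) {
    f <- detect_foci(fl[[i]], mk[[i]], psf_sigma = det$psf_sigma,
                     min_separation = det$min_separation,
                     snr_threshold = det$snr_threshold)
    if (nrow(f)) out[[i]] <- cbind(page = i, time_min = times[i], f)
  }
  foci <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(foci))
    foci <- data.frame(page = integer(0), time_min = numeric(0),
                       cell_id = integer(0), x_px = numeric(0),
                       y_px = numeric(0), axis_coord = numeric(0),
                       brightness = numeric(0), response = numeric(0))
  utils::write.csv(foci, file.path(out_dir, "foci.csv"), row.names = FALSE)
  counts <- do.call(rbind, lapply(seq_along(fl), function(i) {
    labs <- sort(unique(mk[[i]][mk[[i]] > 0]))
    if (!length(labs)) return(NULL)
    n <- vapply(labs, function(L)
      sum(foci$page == i & foci$cell_id == L), integer(1))
    data.frame(cell_id = labs, time_min = times[i], n_foci = n)
  }))
  utils::write.csv(counts, file.path(out_dir, "foci_counts.csv"),
                   row.names = FALSE)
  write_config(config, file.path(out_dir, "config_used.yaml"))
  message(sprintf("detect-foci: %d foci in %d frames -> %s",
                  nrow(foci), length(fl), out_dir))
  invisible(foci)
}

prepare_tracks <- function(config, table) {
  tracks <- link_generations(table)
  tracks <- assign_birth_all(tracks, config$analysis$birth_definition)
  classify_progeny_all(tracks, config$analysis$motion_threshold)
}

#' Run trajectory curation
#'
#' @param config Pipeline config.
#' @param tracks_path Track-table CSV.
#' @param out_dir Output directory for `curation_report.csv`.
#' @return Invisibly, the `curation_report`.
#' @export
run_curate <- function(config = default_config(), tracks_path, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- read_track_table(tracks_path)
  tracks <- prepare_tracks(config, table)
  profiles <- growth_profiles(tracks, config$sim$frame_interval_phase,
                              config$analysis$smoothing_window)
  rep <- apply_filters(tracks, profiles, config_curation(config))
  utils::write.csv(rep$table, file.path(out_dir, "curation_report.csv"),
                   row.names = FALSE)
  write_config(config, file.path(out_dir, "config_used.yaml"))
  for (nm in names(rep$rejected))
    message(sprintf("curate: rejected %s (%s)", nm,
                    paste(rep$rejected[[nm]], collapse = ";")))
  message(sprintf("curate: %d in, %d retained, %d rejected -> %s",
                  nrow(rep$table), length(rep$retained),
                  length(rep$rejected), out_dir))
  invisible(rep)
}

#' Run the full growth analysis
#'
#' Links the tracked table, assigns the configured birth definition,
#' classifies progeny, computes growth profiles, curates, aligns retained
#' cells on cell-cycle units and writes per-cell metrics, the per-type
#' aligned population curves (mean and bootstrap CI), and tempogram
#' matrices. If a focus-count CSV is given, per-cell G1 durations are
#' quantified and included.
#'
#' @param config Pipeline config.
#' @param tracks_path Track-table CSV.
#' @param out_dir Output directory.
#' @param foci_counts_path Optional CSV with `cell_id`, `time_min`, `n_foci`.
#' @return Invisibly, a list with tracks, profiles, curation report, metrics
#'   and per-type `aligned_population` objects.
#' @export
run_analyze <- function(config = default_config(), tracks_path, out_dir,
                        foci_counts_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- read_track_table(tracks_path)
  tracks <- prepare_tracks(config, table)
  profiles <- growth_profiles(tracks, config$sim$frame_interval_phase,
                              config$analysis$smoothing_window)
  rep <- apply_filters(tracks, profiles, config_curation(config))
  g1 <- NULL
  if (!is.null(foci_counts_path)) {
    counts <- utils::read.csv(foci_counts_path)
    g1 <- vapply(names(tracks), function(nm) {
      cc <- counts[counts$cell_id == tracks[[nm]]$cell_id, ]
      if (!nrow(cc)) return(NA_real_)
      g1_from_foci(cc$time_min, cc$n_foci, tracks[[nm]]$birth_time)$g1_duration
    }, numeric(1))
  }
  metrics <- do.call(rbind, lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]; pr <- profiles[[nm]]
    data.frame(cell_id = tr$cell_id, progeny_type = tr$progeny_type,
               birth_definition = tr$birth_definition,
               birth_time = tr$birth_time, a_birth = tr$a_birth,
               a_division = tr$a_division %||% NA_real_,
               dt = tr$dt %||% NA_real_, avg_rate = pr$avg_rate,
               residual_score = pr$residual_score,
               g1_duration = if (is.null(g1)) NA_real_ else g1[[nm]],
               retained = nm %in% rep$retained)
  }))
  utils::write.csv(metrics, file.path(out_dir, "per_cell_metrics.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(rep$table, file.path(out_dir, "curation_report.csv"),
                   row.names = FALSE)
  n_bins <- config$analysis$n_bins
  pops <- list()
  for (type in c("swarmer", "stalked")) {
    ids <- metrics$cell_id[metrics$retained & metrics$progeny_type == type]
    if (length(ids) < 2L) next
    aligned <- lapply(as.character(ids), function(nm) {
      tr <- tracks[[nm]]; pr <- profiles[[nm]]
      align_cell_cycle(pr$inst_rate, tr$times, tr$birth_time,
                       tr$division_time, n_bins)$rate
    })
    pop <- population_mean_curve(aligned, n_boot = config$analysis$n_boot,
                                 alpha = config$analysis$alpha,
                                 seed = config$seed)
    pops[[type]] <- pop
    utils::write.csv(
      data.frame(cc_unit = pop$bin_centers, mean_rate = pop$mean_rate,
                 ci_low = pop$ci_low, ci_high = pop$ci_high,
                 n_cells = pop$n_contrib),
      file.path(out_dir, sprintf("aligned_population_%s.csv", type)),
      row.names = FALSE, na = "")
    dts <- metrics$dt[match(ids, metrics$cell_id)]
    tg <- tempogram(aligned, dts)
    utils::write.csv(cbind(interdivision_min = attr(tg, "interdivision_time"),
                           as.data.frame(unclass(tg))),
                     file.path(out_dir, sprintf("tempogram_%s.csv", type)),
                     row.names = FALSE, na = "")
  }
  write_config(config, file.path(out_dir, "config_used.yaml"))
  message(sprintf("analyze: %d tracks, %d retained (%d swarmer, %d stalked) -> %s",
                  nrow(metrics), sum(metrics$retained),
                  sum(metrics$retained & metrics$progeny_type == "swarmer"),
                  sum(metrics$retained & metrics$progeny_type == "stalked"),
                  out_dir))
  invisible(list(tracks = tracks, profiles = profiles, curation = rep,
                 metrics = metrics, populations = pops))
}

#' Render report figures from an analysis directory
#'
#' Writes a PDF with the aligned population growth-rate curves (mean and
#' bootstrap CI band) and the per-type tempograms.
#'
#' @param analyze_dir Directory written by [run_analyze()].
#' @param out_pdf Output PDF path.
#' @return `out_pdf`, invisibly.
#' @export
run_report <- function(analyze_dir, out_pdf = file.path(analyze_dir, "report.pdf")) {
  grDevices::pdf(out_pdf, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  cols <- c(swarmer = "#1b9e77", stalked = "#7570b3")
  first <- TRUE
  for (type in c("swarmer", "stalked")) {
    f <- file.path(analyze_dir, sprintf("aligned_population_%s.csv", type))
    if (!file.exists(f)) next
    d <- utils::read.csv(f)
    pop <- structure(list(bin_centers = d$cc_unit, mean_rate = d$mean_rate,
                          ci_low = d$ci_low, ci_high = d$ci_high,
                          n_contrib = d$n_cells, n_cells = max(d$n_cells),
                          alpha = 0.05), class = "aligned_population")
    plot(pop, col = cols[[type]], add = !first,
         main = if (first) "Cell-cycle-aligned growth rate" else NULL)
    first <- FALSE
  }
  if (!first)
    graphics::legend("bottomright", names(cols), col = cols, lwd = 2, bty = "n")
  for (type in c("swarmer", "stalked")) {
    f <- file.path(analyze_dir, sprintf("tempogram_%s.csv", type))
    if (!file.exists(f)) next
    d <- utils::read.csv(f)
    tg <- as.matrix(d[, -1, drop = FALSE])
    attr(tg, "interdivision_time") <- d[[1]]
    class(tg) <- c("tempogram", class(tg))
    plot(tg, main = sprintf("Tempogram (%s)", type))
  }
  message(sprintf("report -> %s", out_pdf))
  invisible(out_pdf)
}

arg_value <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) stopf("missing value for %s", flag)
  args[i[1] + 1L]
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `detect-foci`, `curate`, `analyze` and
#' `report` subcommands used by the `ccgrowth` CLI script
#' (`system.file("cli", "ccgrowth.R", package = "ccgrowth")`). Each command
#' validates its inputs, logs parameters and in/out counts, writes its
#' config snapshot, and returns a nonzero status on validation failure.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args) {
  usage <- paste(
    "usage: ccgrowth <command> [options]",
    "  simulate    --out DIR [--config FILE] [--seed N] [--render]",
    "  detect-foci --fluor TIF --mask TIF --out DIR [--config FILE]",
    "  curate      --tracks CSV --out DIR [--config FILE]",
    "  analyze     --tracks CSV --out DIR [--config FILE] [--foci CSV]",
    "  report      --in DIR [--pdf FILE]", sep = "\n")
  status <- tryCatch({
    if (!length(args)) { message(usage); return(invisible(1L)) }
    cmd <- args[1L]; rest <- args[-1L]
    cfg <- read_config(arg_value(rest, "--config"))
    seed <- arg_value(rest, "--seed")
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    switch(cmd,
      "simulate" = run_simulate(cfg, arg_value(rest, "--out"),
                                render_images = "--render" %in% rest),
      "detect-foci" = run_detect_foci(cfg, arg_value(rest, "--fluor"),
                                      arg_value(rest, "--mask"),
                                      arg_value(rest, "--out")),
      "curate" = run_curate(cfg, arg_value(rest, "--tracks"),
                            arg_value(rest, "--out")),
      "analyze" = run_analyze(cfg, arg_value(rest, "--tracks"),
                              arg_value(rest, "--out"),
                              foci_counts_path = arg_value(rest, "--foci")),
      "report" = run_report(arg_value(rest, "--in"),
                            arg_value(rest, "--pdf") %||%
                              file.path(arg_value(rest, "--in"), "report.pdf")),
      stopf("unknown command '%s'\n%s", cmd, usage))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
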