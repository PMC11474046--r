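track_table_columns <- function() {
  c("cell_id", "frame", "time_min", "area_um2", "centroid_x_um",
    "centroid_y_um", "pole1_x", "pole1_y", "pole2_x", "pole2_y",
    "mother_id", "has_stalk", "sep_event", "cyto_event")
}

#' Read a tracked-cell table
#'
#' Reads the package's track-table CSV dialect (one row per cell and frame,
#' UTF-8, '.' decimal separator, exact header) with strict schema
#' validation: a missing column, a duplicated `(cell_id, frame)` key or a
#' non-numeric field is an error naming the offending line. `mother_id` may
#' be empty (founder cells).
#'
#' @param path CSV file path.
#' @return `data.frame` with the columns of the dialect.
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character", check.names = FALSE)
  req <- track_table_columns()
  if (!identical(names(df), req))
    stopf("bad track-table header: expected exactly %s", paste(req, collapse = ","))
  for (col in req) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stopf("non-numeric value '%s' in column %s at line %d",
            v[bad[1]], col, bad[1] + 1L)
    if (col != "mother_id") {
      miss <- which(is.na(num))
      if (length(miss))
        stopf("missing value in column %s at line %d", col, miss[1] + 1L)
    }
    df[[col]] <- num
  }
  for (col in c("cell_id", "frame", "mother_id", "has_stalk",
                "sep_event", "cyto_event"))
    df[[col]] <- as.integer(df[[col]])
  key <- paste(df$cell_id, df$frame)
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("duplicated (cell_id, frame) key at line %d", dup[1] + 1L)
  df
}

#' Write a tracked-cell table
#'
#' @param table `data.frame` in the track-table dialect.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(table, path) {
  req <- track_table_columns()
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stopf("table is missing columns: %s", paste(missing_cols, collapse = ", "))
  out <- table[req]
  for (col in req) {
    v <- out[[col]]
    s <- if (is.double(v)) formatC(v, digits = 17, format = "g")
         else as.character(v)
    s[is.na(v)] <- ""
    out[[col]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a uint16 TIFF stack
#'
#' Integer count images (fluorescence frames or label masks) are stored as
#' 16-bit TIFF pages; values must lie in `[0, 65535]`. Lossless for integer
#' counts.
#'
#' @param stack List of numeric matrices (or a single matrix).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- list(stack)
  pages <- lapply(stack, function(m) {
    m <- round(m)
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a uint16 TIFF stack
#'
#' @param path TIFF path written by [write_tiff_stack()].
#' @return List of integer matrices.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) matrix(as.integer(round(m)), nrow(m)))
}

#' Default pipeline configuration
#'
#' One structured configuration covering every stage: simulation parameters,
#' rendering, focus detection, curation thresholds, and analysis settings
#' (birth definition, cell-cycle bins, bootstrap). Unknown keys in a config
#' file are rejected at load time, and every pipeline command writes the
#' exact config it used next to its outputs.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  sp <- unclass(sim_params())
  rp <- unclass(render_params())
  rp$image_shape <- NULL
  list(
    seed = 1L,
    sim = c(sp, list(n_generations = 3L, n_founders = 20L)),
    render = rp,
    detection = list(psf_sigma = 1.3, min_separation = 3, snr_threshold = 5,
                     pole_fraction = 0.2),
    curation = list(min_duration = 30, min_area_increase = 0.61,
                    rate_upper = 0.015, rate_lower = -0.0025,
                    max_birth_time = NULL, require_complete_lineage = TRUE,
                    drop_uncertain = TRUE, manual_exclusions = NULL),
    analysis = list(birth_definition = "cytokinesis", n_bins = 30L,
                    smoothing_window = 12L, n_boot = 1000L, alpha = 0.05,
                    motion_threshold = 1.0)
  )
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stopf("unknown config key%s: %s", if (length(extra) > 1) "s" else "",
          paste0(path, extra, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]]))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "$"))
  invisible(TRUE)
}

#' Read and validate a pipeline configuration file
#'
#' YAML config; keys absent from the file take their defaults, unknown keys
#' are rejected.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated nested config list.
#' @export
read_config <- function(path = NULL) {
  ref <- default_config()
  if (is.null(path)) return(ref)
  cfg <- yaml::read_yaml(path)
  check_config_keys(cfg, ref)
  out <- utils::modifyList(ref, cfg)
  out$seed <- as.integer(out$seed)
  out
}

#' Write a configuration snapshot
#'
#' @param config Nested config list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_sim_params <- function(config) {
  s <- config$sim
  do.call(sim_params, s[setdiff(names(s), c("n_generations", "n_founders"))])
}

config_render_params <- function(config) do.call(render_params, config$render)

config_curation <- function(config) do.call(curation_config, config$curation)
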