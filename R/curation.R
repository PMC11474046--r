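#' Trajectory curation configuration
#'
#' Thresholds for the explicit trajectory-quality filters: minimum cycle
#' duration, minimum total area increase, bounds on the instantaneous growth
#' rate (evaluated on the smoothed rate series), the complete-lineage
#' requirement, removal of uncertain progeny types, an optional cutoff on
#' pad birth time (used for strain comparisons), and an explicit manual
#' exclusion list. All comparisons are strict as stated, so boundary values
#' are retained.
#'
#' @param min_duration Reject cycles shorter than this (min).
#' @param min_area_increase Reject cells whose `A_d - A_b` is smaller than
#'   this (um^2).
#' @param rate_upper,rate_lower Reject cells with any smoothed instantaneous
#'   rate above/below these bounds (min^-1).
#' @param max_birth_time Reject cells born on the pad later than this (min);
#'   `NULL` disables the rule.
#' @param require_complete_lineage Reject cells lacking a detected mother or
#'   daughters.
#' @param drop_uncertain Reject cells with uncertain progeny type.
#' @param manual_exclusions Character/integer vector of cell ids to drop with
#'   an explicit log entry.
#' @return A `curation_config` list.
#' @export
curation_config <- function(min_duration = 30,
                            min_area_increase = 0.61,
                            rate_upper = 0.015,
                            rate_lower = -0.0025,
                            max_birth_time = NULL,
                            require_complete_lineage = TRUE,
                            drop_uncertain = TRUE,
                            manual_exclusions = NULL) {
  if (!(rate_lower < 0 && 0 < rate_upper))
    stopf("rate bounds must satisfy rate_lower < 0 < rate_upper")
  if (min_duration <= 0) stopf("min_duration must be positive")
  structure(list(min_duration = min_duration,
                 min_area_increase = min_area_increase,
                 rate_upper = rate_upper, rate_lower = rate_lower,
                 max_birth_time = max_birth_time,
                 require_complete_lineage = isTRUE(require_complete_lineage),
                 drop_uncertain = isTRUE(drop_uncertain),
                 manual_exclusions = manual_exclusions),
            class = "curation_config")
}

#' Apply trajectory-quality filters
#'
#' Evaluates every rule of the [curation_config()] on every track and returns
#' a full report: each rejected cell carries one reason code per failed rule
#' (a cell may carry several). Tracks must have the active birth definition
#' assigned ([assign_birth_all()]) and growth profiles computed
#' ([growth_profiles()]); a track without a profile is an error naming it.
#'
#' @param tracks A `cell_track_set` after [assign_birth_all()] (and usually
#'   [classify_progeny_all()]).
#' @param profiles Matching `growth_profiles`.
#' @param config A [curation_config()].
#' @return A `curation_report`: `table` (cell_id, retained, reasons),
#'   `retained` (ids), `rejected` (named list of reason-code vectors).
#' @export
apply_filters <- function(tracks, profiles, config = curation_config()) {
  stopifnot(inherits(tracks, "cell_track_set"))
  cfg <- config
  ids <- names(tracks)
  reasons <- vector("list", length(ids)); names(reasons) <- ids
  for (nm in ids) {
    tr <- tracks[[nm]]
    pr <- profiles[[nm]]
    if (is.null(pr)) stopf("no growth profile for track %s", nm)
    rs <- character(0)
    if (is.na(tr$dt %||% NA) || tr$incomplete_event %||% TRUE ||
        (cfg$require_complete_lineage && !tr$complete))
      rs <- c(rs, "incomplete_lineage")
    if (!is.na(tr$dt %||% NA) && tr$dt < cfg$min_duration)
      rs <- c(rs, "short_cycle")
    if (!is.na(tr$a_division %||% NA) && !is.na(tr$a_birth %||% NA) &&
        (tr$a_division - tr$a_birth) < cfg$min_area_increase)
      rs <- c(rs, "small_area_increase")
    if (any(pr$inst_rate > cfg$rate_upper)) rs <- c(rs, "rate_above_upper")
    if (any(pr$inst_rate < cfg$rate_lower)) rs <- c(rs, "rate_below_lower")
    if (cfg$drop_uncertain && identical(tr$progeny_type, "uncertain"))
      rs <- c(rs, "uncertain_type")
    if (!is.null(cfg$max_birth_time) && !is.na(tr$birth_time %||% NA) &&
        tr$birth_time > cfg$max_birth_time)
      rs <- c(rs, "late_birth")
    if (nm %in% as.character(cfg$manual_exclusions %||% character(0)))
      rs <- c(rs, "manual_exclusion")
    reasons[[nm]] <- rs
  }
  rejected <- reasons[vapply(reasons, length, integer(1)) > 0L]
  retained <- setdiff(ids, names(rejected))
  tab <- data.frame(
    cell_id = ids,
    retained = !(ids %in% names(rejected)),
    reasons = vapply(reasons, paste, "", collapse = ";"),
    row.names = NULL)
  structure(list(table = tab, retained = retained, rejected = rejected,
                 config = cfg),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("Curation: %d retained, %d rejected of %d tracks\n",
              length(x$retained), length(x$rejected), nrow(x$table)))
  if (length(x$rejected)) {
    codes <- table(unlist(x$rejected))
    for (nm in names(codes)) cat(sprintf("  %s: %d\n", nm, codes[[nm]]))
  }
  invisible(x)
}

#' @export
summary.curation_report <- function(object, ...) print(object)
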