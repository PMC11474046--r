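#' Build linked cell tracks from a per-frame track table
#'
#' Groups per-frame records into one `cell_track` per cell and resolves
#' mother/daughter/sister links from the `mother_id` column. Each division
#' must yield exactly two daughters; a mother with more than two is an error
#' naming the offending ids. Cells without a mother (founders) or without
#' daughters (end of movie) are retained but flagged incomplete. Division
#' event bookkeeping needed by [assign_birth()] is precomputed here: the
#' cytokinesis division frame (first frame of the daughters) and the
#' separation division frame (the daughters' shared `sep_event` frame, at
#' which the conceptual predivisional cell's area is the sum of the two
#' daughter compartments).
#'
#' @param table A track table `data.frame` in the package dialect (see
#'   [read_track_table()]).
#' @param frame_interval Imaging interval (min) used to validate times.
#' @return A `cell_track_set`: named list of `cell_track` objects.
#' @export
link_generations <- function(table, frame_interval = NULL) {
  req <- track_table_columns()
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stopf("track table is missing columns: %s", paste(missing_cols, collapse = ", "))
  key <- paste(table$cell_id, table$frame)
  if (anyDuplicated(key))
    stopf("duplicated (cell_id, frame) pairs: %s",
          paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
                collapse = "; "))
  by_cell <- split(seq_len(nrow(table)), table$cell_id)
  tracks <- lapply(by_cell, function(idx) {
    d <- table[idx[order(table$frame[idx])], ]
    if (any(d$area_um2 <= 0)) stopf("non-positive area for cell %s", d$cell_id[1])
    sep_f <- d$frame[d$sep_event == 1]
    structure(list(
      cell_id = as.integer(d$cell_id[1]),
      frames = d$frame, times = d$time_min, areas = d$area_um2,
      centroid = cbind(d$centroid_x_um, d$centroid_y_um),
      poles = cbind(d$pole1_x, d$pole1_y, d$pole2_x, d$pole2_y),
      mother_id = if (is.na(d$mother_id[1])) NA_integer_ else as.integer(d$mother_id[1]),
      has_stalk = as.logical(d$has_stalk[1]),
      cyto_frame = d$frame[1],
      sep_frame = if (length(sep_f)) sep_f[1] else d$frame[1],
      daughter_ids = integer(0), sister_id = NA_integer_,
      progeny_type = "uncertain",
      div_cyto_frame = NA_integer_, div_cyto_time = NA_real_,
      div_sep_frame = NA_integer_, div_sep_time = NA_real_,
      div_sep_area = NA_real_,
      complete = FALSE, orphan = FALSE
    ), class = "cell_track")
  })
  names(tracks) <- vapply(tracks, function(tr) as.character(tr$cell_id), "")
  mothers <- vapply(tracks, function(tr) tr$mother_id, integer(1))
  kids <- split(vapply(tracks, `[[`, integer(1), "cell_id"), mothers)
  for (m in names(kids)) {
    ids <- unname(kids[[m]])
    if (length(ids) > 2L)
      stopf("mother %s has %d daughters (ids: %s); expected exactly 2",
            m, length(ids), paste(ids, collapse = ", "))
    if (!m %in% names(tracks)) next  # mother outside the table: leave orphans
    if (length(ids) == 2L) {
      tracks[[as.character(ids[1])]]$sister_id <- ids[2]
      tracks[[as.character(ids[2])]]$sister_id <- ids[1]
    }
    tracks[[m]]$daughter_ids <- ids
    d1 <- tracks[[as.character(ids[1])]]
    tracks[[m]]$div_cyto_frame <- d1$cyto_frame
    tracks[[m]]$div_cyto_time <- d1$times[1]
    if (length(ids) == 2L) {
      d2 <- tracks[[as.character(ids[2])]]
      fsep <- d1$sep_frame
      i1 <- match(fsep, d1$frames); i2 <- match(fsep, d2$frames)
      if (!is.na(i1) && !is.na(i2)) {
        tracks[[m]]$div_sep_frame <- fsep
        tracks[[m]]$div_sep_time <- d1$times[i1]
        tracks[[m]]$div_sep_area <- d1$areas[i1] + d2$areas[i2]
      }
    }
  }
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    tracks[[nm]]$orphan <- is.na(tr$mother_id)
    tracks[[nm]]$complete <- !is.na(tr$mother_id) && length(tr$daughter_ids) == 2L
  }
  structure(tracks, class = "cell_track_set")
}

#' @export
print.cell_track_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("Cell track set: %d cells (%d with complete lineage)\n",
              n, sum(vapply(x, `[[`, logical(1), "complete"))))
  invisible(x)
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("Cell %s: frames %d-%d, mother %s, %d daughter(s), type %s\n",
              x$cell_id, min(x$frames), max(x$frames),
              ifelse(is.na(x$mother_id), "none", x$mother_id),
              length(x$daughter_ids), x$progeny_type))
  invisible(x)
}

#' Assign the active birth definition to a track
#'
#' Computes the birth frame, birth area `A_b`, division area `A_d` and
#' interdivision time `dt` under one of the two birth conventions:
#' `"cytokinesis"` (birth at the mask split in the mother, i.e. the track's
#' first frame; quantities under this convention carry the field's asterisk
#' notation) or `"separation"` (birth at the last frame before visible
#' daughter separation, the classical convention). Division is the matching
#' event of the cell's own daughters; under the separation convention `A_d`
#' is the area at the frame before the daughters separate, summed over the
#' two already-split daughter compartments. Tracks lacking the division event
#' are flagged incomplete (`A_d` and `dt` are `NA`).
#'
#' @param track A `cell_track` from [link_generations()].
#' @param defn `"separation"` or `"cytokinesis"`.
#' @return The track with `birth_frame`, `birth_time`, `division_time`,
#'   `a_birth`, `a_division`, `dt` and `birth_definition` fields set.
#' @export
assign_birth <- function(track, defn = c("cytokinesis", "separation")) {
  defn <- match.arg(defn)
  tr <- track
  if (defn == "cytokinesis") {
    bf <- tr$cyto_frame
    div_t <- tr$div_cyto_time
    a_d <- if (!is.na(div_t)) tr$areas[length(tr$areas)] else NA_real_
  } else {
    bf <- tr$sep_frame
    div_t <- tr$div_sep_time
    a_d <- tr$div_sep_area
  }
  i <- match(bf, tr$frames)
  if (is.na(i)) stopf("birth frame %s not present in track %s", bf, tr$cell_id)
  tr$birth_definition <- defn
  tr$birth_frame <- bf
  tr$birth_time <- tr$times[i]
  tr$a_birth <- tr$areas[i]
  tr$division_time <- div_t
  tr$a_division <- a_d
  tr$dt <- if (!is.na(div_t)) div_t - tr$times[i] else NA_real_
  tr$incomplete_event <- is.na(div_t)
  tr
}

#' Apply a birth definition to every track in a set
#'
#' @param tracks A `cell_track_set`.
#' @inheritParams assign_birth
#' @return The set with all tracks processed by [assign_birth()].
#' @export
assign_birth_all <- function(tracks, defn = c("cytokinesis", "separation")) {
  defn <- match.arg(defn)
  structure(lapply(tracks, assign_birth, defn = defn),
            class = "cell_track_set", names = names(tracks))
}

net_displacement <- function(track, from_frame, n_frames = 3L) {
  i0 <- match(from_frame, track$frames)
  if (is.na(i0)) i0 <- 1L
  i1 <- min(i0 + n_frames, length(track$frames))
  if (i1 <= i0) return(NA_real_)
  sqrt(sum((track$centroid[i1, ] - track$centroid[i0, ])^2))
}

#' Rule-based swarmer/stalked progeny classification
#'
#' Mechanized version of the visual classification rule: a cell is stalked if
#' it carries a visible stalk, or if its (stalk-free) sister moved
#' considerably after separation; it is swarmer if it is itself motile and
#' lacks a stalk. When both stalk-free siblings move, or neither does, the
#' cell is left uncertain (uncertain cells are removed downstream). Motion is
#' the net centroid displacement over the `n_frames` frames following the
#' separation event.
#'
#' @param track,sister Sibling `cell_track`s.
#' @param motion_threshold Net displacement (um) above which a cell counts as
#'   motile.
#' @param n_frames Frames after separation over which displacement is taken.
#' @return `"swarmer"`, `"stalked"` or `"uncertain"`.
#' @export
classify_progeny <- function(track, sister, motion_threshold = 1.0,
                             n_frames = 3L) {
  if (isTRUE(track$has_stalk)) return("stalked")
  own <- net_displacement(track, track$sep_frame, n_frames)
  sis <- if (!is.null(sister)) net_displacement(sister, sister$sep_frame, n_frames)
         else NA_real_
  own_m <- !is.na(own) && own > motion_threshold
  sis_m <- !is.na(sis) && sis > motion_threshold
  if (sis_m && own_m) return("uncertain")
  if (sis_m) return("stalked")
  if (own_m) return("swarmer")
  "uncertain"
}

#' Classify every sibling pair in a track set
#'
#' @param tracks A `cell_track_set`.
#' @inheritParams classify_progeny
#' @return The set with `progeny_type` set on each track.
#' @export
classify_progeny_all <- function(tracks, motion_threshold = 1.0, n_frames = 3L) {
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    sis <- if (!is.na(tr$sister_id)) tracks[[as.character(tr$sister_id)]] else NULL
    tracks[[nm]]$progeny_type <-
      classify_progeny(tr, sis, motion_threshold, n_frames)
  }
  tracks
}
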