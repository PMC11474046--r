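# Shared fixtures: hand-constructed tracks and small cached simulations.

# A cell_track with explicit birth/division bookkeeping, bypassing the
# linking stage, for unit tests of downstream modules.
manual_track <- function(id, mu = 0.007, dt_min = 60, a0 = 1.5,
                         frame_interval = 1.5, complete = TRUE,
                         jump_at = NULL, jump_factor = 1,
                         type = "swarmer", birth_time = 0) {
  n <- round(dt_min / frame_interval) + 1L
  times <- birth_time + (seq_len(n) - 1L) * frame_interval
  areas <- a0 * exp(mu * (times - birth_time))
  if (!is.null(jump_at)) areas[jump_at:n] <- areas[jump_at:n] * jump_factor
  structure(list(
    cell_id = id, frames = seq_len(n) - 1L, times = times, areas = areas,
    centroid = cbind(rep(0, n), rep(0, n)),
    poles = cbind(-1, 0, 1, 0)[rep(1, n), , drop = FALSE],
    mother_id = if (complete) id + 1000L else NA_integer_,
    has_stalk = FALSE, cyto_frame = 0L, sep_frame = 0L,
    daughter_ids = if (complete) c(id + 2000L, id + 2001L) else integer(0),
    sister_id = NA_integer_, progeny_type = type,
    complete = complete, orphan = !complete,
    birth_definition = "cytokinesis", birth_frame = 0L,
    birth_time = birth_time, division_time = if (complete) birth_time + dt_min else NA_real_,
    a_birth = areas[1L], a_division = if (complete) areas[n] else NA_real_,
    dt = if (complete) dt_min else NA_real_,
    incomplete_event = !complete
  ), class = "cell_track")
}

track_set <- function(...) {
  trs <- list(...)
  names(trs) <- vapply(trs, function(t) as.character(t$cell_id), "")
  structure(trs, class = "cell_track_set")
}

# Small simulation reused across tests (built once per test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_lineage(sim_params(seed = 42L), n_generations = 3L,
                                 n_founders = 30L)
    cache
  }
})

analyzed_tracks <- function(sim, defn = "cytokinesis") {
  classify_progeny_all(assign_birth_all(link_generations(sim$table), defn))
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of the
# rank assignments (tie-free samples only).
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ranks <- rank(pooled)
  us <- apply(combs, 2L, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  mid <- n1 * n2 / 2
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# Direct ECDF scan for the two-sample KS statistic.
ks_enum_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 1.0)))
}

# Six tracks, each violating exactly one rule except one clean cell.
curation_fixture <- function() {
  track_set(
    manual_track(1, mu = 0.007, dt_min = 60),                      # clean
    manual_track(2, mu = 0.0138, dt_min = 25),                     # too short
    manual_track(3, mu = 0.004, dt_min = 60),                      # small increase
    manual_track(4, mu = 0.007, dt_min = 60, jump_at = 20,
                 jump_factor = 1.5),                               # rate too high
    manual_track(5, mu = 0.009, dt_min = 90, jump_at = 30,
                 jump_factor = 0.72),                              # rate too low
    manual_track(6, mu = 0.007, dt_min = 60, complete = FALSE)     # no lineage
  )
}
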