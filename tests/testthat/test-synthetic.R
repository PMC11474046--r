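test_that("growth-rate profile is piecewise linear with the stated landmarks", {
  p <- sim_params(baseline_rate = 0.008, dip_depth = 0.5, recovery_width = 30)
  expect_equal(growth_rate_profile(0, p, 30), 0.008)    # no decline yet at birth
  expect_equal(growth_rate_profile(30, p, 30), 0.004)   # trough = mu0 * (1 - d)
  expect_equal(growth_rate_profile(45, p, 30), 0.006)   # recovery midpoint
  expect_equal(growth_rate_profile(120, p, 30), 0.008)  # recovered
  flat <- sim_params(baseline_rate = 0.008, dip_depth = 0)
  expect_equal(growth_rate_profile(c(0, 10, 50), flat, 30), rep(0.008, 3))
  expect_equal(growth_rate_profile(c(0, 10), p, 0), rep(0.008, 2))
  expect_error(growth_rate_profile(-1, p, 30), "non-negative")
})

test_that("closed-form rate integral matches numerical quadrature", {
  p <- sim_params(baseline_rate = 0.0077, dip_depth = 0.4, recovery_width = 25,
                  trough_offset = 5)
  for (tt in c(3, 20, 41.3, 44.9, 60, 66, 150)) {
    num <- stats::integrate(function(u) growth_rate_profile(u, p, 40), 0, tt,
                            rel.tol = 1e-12, subdivisions = 2000L)$value
    expect_equal(ccgrowth:::rate_integral(tt, p, 40), num, tolerance = 1e-8)
  }
})

test_that("noiseless trajectories are exact exponentials of the rate integral", {
  p <- sim_params(seed = 5, area_noise_cv = 0, dip_depth = 0.4)
  sim <- simulate_lineage(p, n_generations = 2, n_founders = 3)
  for (i in seq_len(nrow(sim$truth))) {
    cell <- sim$truth[i, ]
    rows <- sim$table[sim$table$cell_id == cell$cell_id, ]
    trel <- rows$time_min - cell$birth_time_cyto
    pc <- ccgrowth:::cell_dip_params(p, cell$g1_duration_true)
    expected <- cell$birth_area_true *
      exp(ccgrowth:::rate_integral(trel, pc, cell$g1_duration_true))
    expect_equal(rows$area_um2, expected, tolerance = 1e-12)
  }
})

test_that("dip-free noiseless cells grow as single exponentials at mu0", {
  p <- sim_params(seed = 2, dip_depth = 0, area_noise_cv = 0,
                  baseline_rate = 0.006)
  sim <- simulate_lineage(p, n_generations = 2, n_founders = 2)
  for (cid in sim$truth$cell_id) {
    rows <- sim$table[sim$table$cell_id == cid, ]
    rate <- instantaneous_growth_rate(rows$area_um2, p$frame_interval_phase)
    expect_equal(rate, rep((exp(0.006 * 1.5) - 1) / 1.5, length(rate)),
                 tolerance = 1e-10)
  }
})

test_that("division conserves area and respects the asymmetry ratio", {
  p <- sim_params(seed = 8, area_noise_cv = 0)
  sim <- simulate_lineage(p, n_generations = 3, n_founders = 4)
  tr <- sim$truth
  mothers <- tr$cell_id[tr$generation < 3]
  for (m in mothers) {
    kids <- tr[!is.na(tr$mother_id) & tr$mother_id == m, ]
    expect_equal(nrow(kids), 2L)
    mom <- tr[tr$cell_id == m, ]
    a_div <- mom$birth_area_true *
      exp(ccgrowth:::rate_integral(
        mom$division_time - mom$birth_time_cyto,
        ccgrowth:::cell_dip_params(p, mom$g1_duration_true),
        mom$g1_duration_true))
    expect_equal(sum(kids$birth_area_true), a_div, tolerance = 1e-12)
    sw <- kids[kids$progeny_type == "swarmer", ]
    expect_equal(sw$birth_area_true / a_div, p$division_ratio, tolerance = 1e-12)
    expect_lt(sw$birth_area_true, kids[kids$progeny_type == "stalked", "birth_area_true"])
  }
  # symmetric split -> equal sibling birth areas
  sym <- simulate_lineage(sim_params(seed = 8, area_noise_cv = 0,
                                     division_ratio = 0.5),
                          n_generations = 2, n_founders = 3)
  kids <- sym$truth[!is.na(sym$truth$mother_id), ]
  for (m in unique(kids$mother_id)) {
    pair <- kids$birth_area_true[kids$mother_id == m]
    expect_equal(pair[1], pair[2], tolerance = 1e-12)
  }
})

test_that("birth events keep cytokinesis before separation before division", {
  sim <- shared_sim()
  tr <- sim$truth
  expect_true(all(tr$birth_time_cyto <= tr$birth_time_sep))
  expect_true(all(tr$birth_time_sep < tr$division_time, na.rm = TRUE))
  expect_true(all(tr$g1_duration_true >= 0))
  expect_true(all(tr$sep_offset >= 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- sim_params(seed = 77)
  s1 <- simulate_lineage(p, n_generations = 3, n_founders = 5)
  s2 <- simulate_lineage(p, n_generations = 3, n_founders = 5)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_lineage(sim_params(seed = 78), 3, 5)
  expect_false(identical(s1$table$area_um2, s3$table$area_um2))
})

test_that("longer swarmer G1 lowers swarmer average growth rate below stalked", {
  p <- sim_params(seed = 12, baseline_rate = 0.006, dip_depth = 0.4,
                  g1_mean_swarmer = 40, g1_mean_stalked = 12)
  sim <- simulate_lineage(p, n_generations = 3, n_founders = 50)
  tracks <- analyzed_tracks(sim)
  keep <- vapply(tracks, function(t) t$complete, TRUE)
  avg <- vapply(tracks, function(t)
    if (t$complete) average_growth_rate(t$a_birth, t$a_division, t$dt)
    else NA_real_, 1.0)
  type <- vapply(tracks, `[[`, "", "progeny_type")
  expect_lt(mean(avg[keep & type == "swarmer"]),
            mean(avg[keep & type == "stalked"]))
})

test_that("simulated focus tracks switch from one to two foci at G1 end", {
  p <- sim_params(seed = 1)
  cell <- data.frame(cell_id = 1L, birth_time_cyto = 0,
                     g1_duration_true = 9, division_time = 60)
  ft <- simulate_foci_track(cell, p)
  expect_equal(ft$times[1:4], c(0, 3, 6, 9))
  expect_equal(ft$counts[1:4], c(1L, 1L, 1L, 2L))
  # no G1: two foci from the first frame
  ft0 <- simulate_foci_track(transform(cell, g1_duration_true = 0), p)
  expect_equal(ft0$counts[1], 2L)
  # G1 longer than the cycle: never reaches two foci
  ftl <- simulate_foci_track(transform(cell, g1_duration_true = 120), p)
  expect_true(all(ftl$counts == 1L))
  expect_true(all(ft$foci$axis_coord >= 0 & ft$foci$axis_coord <= 1))
})
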