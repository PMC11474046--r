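test_that("sliding-average smoothing follows the symmetric shrinking-window rule", {
  expect_equal(smooth_area(rep(3, 20), 12), rep(3, 20))
  lin <- seq(1, 5, length.out = 40)
  expect_equal(smooth_area(lin, 12)[7:34], lin[7:34])  # interior of a line
  # window 2 -> half-width 1; ends shrink to the point itself
  expect_equal(smooth_area(c(1, 2, 4, 8), 2),
               c(1, mean(c(1, 2, 4)), mean(c(2, 4, 8)), 8))
  expect_error(smooth_area(1:5, 0), "window")
  expect_error(smooth_area(3), "2 frames")
})

test_that("instantaneous rate is the area-normalized forward difference", {
  geo <- 2 * 1.1^(0:10)
  expect_equal(instantaneous_growth_rate(geo, 1), rep(0.1, 10))
  expect_equal(instantaneous_growth_rate(rep(4, 6), 1.5), rep(0, 5))
  # noiseless exponential: closed form (e^{mu dt} - 1)/dt at every step
  mu <- 0.006; dt <- 1.5
  a <- 1.7 * exp(mu * dt * (0:80))
  expect_equal(instantaneous_growth_rate(a, dt),
               rep((exp(mu * dt) - 1) / dt, 80), tolerance = 1e-12)
  expect_error(instantaneous_growth_rate(c(1, -1, 2), 1), "positive")
})

test_that("average growth rate is ln(Ad/Ab)/dt", {
  expect_equal(average_growth_rate(1, 1, 30), 0)
  expect_equal(average_growth_rate(2, 4, 60), log(2) / 60)
  # round-trip on a noiseless exponential cell
  mu <- 0.008
  tr <- manual_track(1, mu = mu, dt_min = 90)
  expect_equal(average_growth_rate(tr$a_birth, tr$a_division, tr$dt), mu,
               tolerance = 1e-9)
  expect_error(average_growth_rate(0, 1, 1), "positive")
})

test_that("exponential-fit residual score separates exponential from non-exponential growth", {
  t <- (0:60) * 1.5
  expect_lt(exp_fit_residuals(2 * exp(0.007 * t), t), 1e-10)
  expect_gt(exp_fit_residuals(2 + 0.05 * t, t), 0)   # linear growth
  expect_error(exp_fit_residuals(c(1, 2, 3), c(5, 5, 5)), "degenerate")

  # cells with a G1 dip fit a single exponential worse than dip-free cells
  dip <- simulate_lineage(sim_params(seed = 9, dip_depth = 0.4,
                                     g1_mean_swarmer = 40, g1_mean_stalked = 40),
                          n_generations = 2, n_founders = 25)
  flat <- simulate_lineage(sim_params(seed = 9, dip_depth = 0),
                           n_generations = 2, n_founders = 25)
  score <- function(sim) {
    trs <- analyzed_tracks(sim)
    founders <- trs[vapply(trs, function(t) is.na(t$mother_id), TRUE)]
    vapply(founders, function(t) exp_fit_residuals(t$areas, t$times), 1.0)
  }
  expect_gt(median(score(dip)), median(score(flat)))
})

test_that("estimator cross-consistency on noiseless exponentials", {
  for (mu in c(0.004, 0.008)) {
    t <- (0:100) * 1.5
    a <- 1.5 * exp(mu * t)
    avg <- average_growth_rate(a[1], a[101], t[101] - t[1])
    slope <- unname(stats::lm.fit(cbind(1, t), log(a))$coefficients[2])
    inst <- instantaneous_growth_rate(a, 1.5)
    mu_from_inst <- log(1 + mean(inst) * 1.5) / 1.5  # invert forward difference
    expect_equal(avg, mu, tolerance = 1e-9)
    expect_equal(slope, mu, tolerance = 1e-9)
    expect_equal(mu_from_inst, mu, tolerance = 1e-6)
  }
})

test_that("growth profile bundles the per-cell computations", {
  tr <- manual_track(7, mu = 0.0077, dt_min = 75)
  pr <- growth_profile(tr, frame_interval = 1.5, window = 12)
  expect_length(pr$inst_rate, length(tr$areas) - 1L)
  expect_equal(pr$avg_rate, 0.0077, tolerance = 1e-9)
  expect_lt(pr$residual_score, 1e-10)
  inc <- manual_track(8, complete = FALSE)
  expect_true(is.na(growth_profile(inc)$avg_rate))
})
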