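test_that("cell-cycle alignment maps steps into (0, 1] and is scale-free", {
  n <- 40
  times <- (0:n) * 1.5
  rate <- rep(0.007, n)
  al <- align_cell_cycle(rate, times, 0, n * 1.5, n_bins = 30)
  expect_equal(al$rate[!is.na(al$rate)],
               rep(0.007, sum(!is.na(al$rate))))  # constant rate -> constant bins
  # first step midpoint lands in (0, 1/n]
  cc1 <- (times[1] + times[2]) / 2 / (n * 1.5)
  expect_true(cc1 > 0 && cc1 <= 1 / n)
  al2 <- align_cell_cycle(rate, times * 7, 0, n * 1.5 * 7, n_bins = 30)
  expect_identical(al$rate, al2$rate)
  expect_error(align_cell_cycle(rate, times, 10, 10), "cycle")
})

test_that("population curve: identical cells give zero-width CI; sparse bins flagged", {
  v <- c(0.006, 0.005, NA, 0.007)
  pop <- population_mean_curve(list(v, v, v), n_boot = 200, seed = 1)
  expect_equal(pop$ci_low[c(1, 2, 4)], v[c(1, 2, 4)])
  expect_equal(pop$ci_high[c(1, 2, 4)], v[c(1, 2, 4)])
  expect_true(is.na(pop$ci_low[3]))      # <2 contributing cells
  expect_true(is.na(pop$mean_rate[3]) || pop$n_contrib[3] == 0)
  pop2 <- population_mean_curve(list(v, v, v), n_boot = 200, seed = 1)
  expect_identical(pop$ci_low, pop2$ci_low)
  expect_error(population_mean_curve(list(v)), "2 cells")
})

test_that("tempogram rows are sorted by interdivision time", {
  vs <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  tg <- tempogram(vs, c(50, 30, 40))
  expect_equal(dim(tg), c(3L, 2L))
  expect_equal(unname(unclass(tg)[, 1]), c(3, 5, 1))  # 30, 40, 50 order
  expect_equal(attr(tg, "interdivision_time"), c(30, 40, 50))
})

test_that("tempogram on simulated cells shows the long-G1 early-cycle slowdown", {
  sim <- shared_sim()
  tracks <- analyzed_tracks(sim)
  keep <- names(tracks)[vapply(tracks, function(t) t$complete, TRUE)]
  g1 <- sim$truth$g1_duration_true[match(as.integer(keep), sim$truth$cell_id)]
  aligned <- lapply(keep, function(nm) {
    tr <- tracks[[nm]]
    pr <- growth_profile(tr)
    align_cell_cycle(pr$inst_rate, tr$times, tr$birth_time, tr$division_time,
                     n_bins = 30)$rate
  })
  mat <- do.call(rbind, aligned)
  early <- rowMeans(mat[, 1:10], na.rm = TRUE)
  long_g1 <- g1 > median(g1); short_g1 <- !long_g1
  expect_lt(mean(early[long_g1]), mean(early[short_g1]))
})

test_that("G1 binning follows lower-inclusive interval rules with exclusion logging", {
  res <- bin_by_g1(c(10, 40, 25), list(c(4.5, 19.5), c(33, 90)))
  expect_equal(res$groups[[1]], 1L)
  expect_equal(res$groups[[2]], 2L)
  expect_equal(res$excluded, 3L)
  # boundary semantics: lo inclusive, hi exclusive, top edge inclusive
  res2 <- bin_by_g1(c(4.5, 19.5, 90), list(c(4.5, 19.5), c(33, 90)))
  expect_equal(res2$groups[[1]], 1L)
  expect_equal(res2$groups[[2]], 3L)
  expect_equal(res2$excluded, 2L)
  expect_error(bin_by_g1(1:3, list(c(0, 10), c(5, 20))), "overlap")
  empty <- bin_by_g1(numeric(0), list(c(0, 10)))
  expect_length(empty$groups[[1]], 0L)

  set.seed(2)
  g1 <- rgamma(91, shape = 4, scale = 10)
  ter <- bin_by_g1(g1, g1_tertile_edges(g1))
  sizes <- lengths(ter$groups)
  expect_length(ter$excluded, 0L)
  expect_lte(diff(range(sizes)), 1L)
})
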