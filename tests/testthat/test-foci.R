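single_cell_frame <- function(foci_um = NULL, noise = "none", amp = 400,
                              seed = 1L) {
  cells <- data.frame(cell_id = 1L, pole1_x = 1.0, pole1_y = 2.0,
                      pole2_x = 5.0, pole2_y = 2.0)
  rp <- render_params(pixel_size = 0.1, psf_sigma = 1.2, background_level = 100,
                      cell_level = 60, focus_amplitude = amp,
                      noise_model = noise, image_shape = c(40, 60))
  render_frame(cells, foci_um, rp, seed = seed)
}

test_that("rendered frames have rod masks and Gaussian foci where expected", {
  fm <- single_cell_frame()
  expect_true(all(fm$fluor[fm$mask == 0] == 100))          # flat background
  expect_true(all(fm$fluor[fm$mask == 1] == 160))          # diffuse cell signal
  # one focus, zero noise: image argmax within 1 px of the focus
  fm1 <- single_cell_frame(data.frame(cell_id = 1, x_um = 3.0, y_um = 2.0))
  pk <- which(fm1$fluor == max(fm1$fluor), arr.ind = TRUE)
  expect_lte(abs(pk[1, "col"] - (3.0 / 0.1 + 0.5)), 1)
  expect_lte(abs(pk[1, "row"] - (2.0 / 0.1 + 0.5)), 1)
  expect_error(single_cell_frame(data.frame(cell_id = 1, x_um = 50, y_um = 2)),
               "outside")
})

test_that("spot detection finds rendered foci and respects the merge radius", {
  expect_equal(nrow(detect_foci(matrix(5, 30, 30), matrix(0L, 30, 30))), 0L)
  blank <- single_cell_frame()
  expect_equal(nrow(detect_foci(blank$fluor, blank$mask, psf_sigma = 1.2)), 0L)
  expect_error(detect_foci(matrix(0, 5, 5), matrix(0L, 4, 5)), "shape")

  fm1 <- single_cell_frame(data.frame(cell_id = 1, x_um = 3.0, y_um = 2.0),
                           noise = "poisson")
  f <- detect_foci(fm1$fluor, fm1$mask, psf_sigma = 1.2)
  expect_equal(nrow(f), 1L)
  expect_lte(abs(f$x_px - 30.5), 1)
  expect_lte(abs(f$y_px - 20.5), 1)
  expect_gt(f$brightness, 0)

  # two foci 6 px (0.6 um) apart: resolved at min_separation 3, merged at 10
  two <- single_cell_frame(data.frame(cell_id = 1, x_um = c(2.7, 3.3),
                                      y_um = 2.0))
  f3 <- detect_foci(two$fluor, two$mask, psf_sigma = 1.2, min_separation = 3)
  f10 <- detect_foci(two$fluor, two$mask, psf_sigma = 1.2, min_separation = 10)
  expect_equal(nrow(f3), 2L)
  expect_equal(nrow(f10), 1L)
})

test_that("detection count is monotone in the threshold and translation-equivariant", {
  fm <- single_cell_frame(data.frame(cell_id = 1, x_um = c(2.0, 4.0), y_um = 2.0),
                          noise = "poisson")
  counts <- vapply(c(1, 3, 5, 8, 20, 1000),
                   function(k) nrow(detect_foci(fm$fluor, fm$mask,
                                                psf_sigma = 1.2,
                                                snr_threshold = k)), 1L)
  expect_true(all(diff(counts) <= 0))

  f0 <- detect_foci(fm$fluor, fm$mask, psf_sigma = 1.2)
  dy <- 5L; dx <- 7L
  big_f <- matrix(100, 40 + dy, 60 + dx)
  big_m <- matrix(0L, 40 + dy, 60 + dx)
  big_f[dy + seq_len(40), dx + seq_len(60)] <- fm$fluor
  big_m[dy + seq_len(40), dx + seq_len(60)] <- fm$mask
  f1 <- detect_foci(big_f, big_m, psf_sigma = 1.2)
  expect_equal(nrow(f1), nrow(f0))
  expect_equal(sort(f1$x_px), sort(f0$x_px) + dx)
  expect_equal(sort(f1$y_px), sort(f0$y_px) + dy)
})

test_that("G1 duration follows the two-focus rule on the fluorescence grid", {
  g <- g1_from_foci(c(0, 3, 6, 9), c(1, 1, 1, 2), birth_time = 0)
  expect_equal(g$g1_duration, 9)
  expect_false(g$censored)
  expect_equal(g1_from_foci(c(0, 3), c(2, 2), 0)$g1_duration, 0)
  cen <- g1_from_foci(c(0, 3, 6), c(1, 1, 1), 0)
  expect_true(cen$censored)
  expect_true(is.na(cen$g1_duration))
  # birth between frames: duration measured from birth, not from the frame
  expect_equal(g1_from_foci(c(0, 3, 6, 9), c(1, 1, 1, 2), 2)$g1_duration, 7)
})

test_that("G1 recovery from simulated counts is within one fluorescence frame", {
  sim <- shared_sim()
  foci <- simulate_foci(sim)
  tracks <- assign_birth_all(link_generations(sim$table), "cytokinesis")
  ok <- sim$truth$complete
  err <- vapply(sim$truth$cell_id[ok], function(cid) {
    ft <- foci[[as.character(cid)]]
    tr <- tracks[[as.character(cid)]]
    rec <- g1_from_foci(ft$times, ft$counts, tr$birth_time)$g1_duration
    abs(rec - sim$truth$g1_duration_true[sim$truth$cell_id == cid])
  }, 1.0)
  expect_gte(mean(err <= 3 + 1e-9, na.rm = TRUE), 0.9)
})

test_that("polarity classification partitions foci by pole occupancy", {
  expect_equal(classify_polarity(c(0.05, 0.95)), "bipolar")
  expect_equal(classify_polarity(0.9), "unipolar")
  expect_equal(classify_polarity(0.5), "other")
  expect_equal(classify_polarity(numeric(0)), "other")
  expect_equal(classify_polarity(c(0.3, 0.6), pole_fraction = 0.45), "bipolar")
})
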