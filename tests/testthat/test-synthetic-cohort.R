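test_that("cohort spec validates probabilities, priors and the seed", {
  expect_error(cohort_spec(seed = 1, lesions_per_patient_weights = c(1, 1, 1)),
               "summing to 1")
  bad <- kinetic_priors_histopathology()
  bad$ms_median[1] <- -1
  expect_error(cohort_spec(seed = 1, priors = bad), "positive")
  expect_error(cohort_spec(n_patients = 125), "seed")
})

test_that("lesion counts follow the per-patient weights", {
  spec <- cohort_spec(seed = 5)
  truth <- sample_cohort(spec)
  sizes <- table(table(truth$patient_id))
  expect_equal(length(unique(truth$patient_id)), 125)
  # expected lesion count 142 = 111 + 2*11 + 3*3; allow multinomial spread
  expect_gt(nrow(truth), 125)
  expect_lt(abs(nrow(truth) - 142), 25)
  expect_lte(max(table(truth$patient_id)), 3)
  one <- sample_cohort(cohort_spec(n_patients = 1,
                                   lesions_per_patient_weights = c(1, 0, 0),
                                   seed = 2))
  expect_equal(nrow(one), 1L)
})

test_that("sampling is deterministic for a fixed seed", {
  a <- sample_cohort(cohort_spec(seed = 31))
  b <- sample_cohort(cohort_spec(seed = 31))
  expect_identical(a, b)
  c <- sample_cohort(cohort_spec(seed = 32))
  expect_false(identical(a, c))
})

test_that("log-normal kinetic draws match their prior medians at large n", {
  spec <- cohort_spec(n_patients = 20000,
                      priors = kinetic_priors_histopathology(), seed = 77)
  truth <- sample_cohort(spec)
  inv <- truth$histopathology == "invasive"
  expect_gt(sum(inv), 10000)
  expect_equal(stats::median(truth$ms_true[inv]), 0.030, tolerance = 0.02)
  expect_equal(stats::median(truth$bat_true[inv]), 21.9, tolerance = 0.02)
  expect_equal(stats::median(truth$ms_true[!inv]), 0.013, tolerance = 0.05)
  # label proportions within binomial error of the class frequencies
  expect_equal(mean(inv), 124 / 142, tolerance = 0.02)
  expect_equal(mean(truth$lesion_type[inv] == "mass"), 91 / 124,
               tolerance = 0.03)
})

test_that("the truth curve is piecewise linear-rise/exponential-washout", {
  truth <- simple_truth(bat = 20, ms = 0.03, peak = 30)
  expect_equal(true_concentration_curve(truth, c(0, 25)), c(0, 0.15))
  expect_equal(true_concentration_curve(truth, c(10, 20)), c(0, 0))
  # continuity at the peak and washout beyond it
  eps <- 1e-9
  cc <- true_concentration_curve(truth, c(30 - eps, 30, 30 + eps))
  expect_equal(cc[1], cc[2], tolerance = 1e-6)
  expect_lt(true_concentration_curve(truth, 60), 0.3)
})

test_that("analytic slope and onset of generated truths are self-consistent", {
  spec <- cohort_spec(n_patients = 40, seed = 13)
  truth <- sample_cohort(spec)
  tgrid <- seq(0, 70, by = 0.01)
  for (i in seq_len(min(nrow(truth), 30))) {
    cc <- true_concentration_curve(truth[i, ], tgrid)
    ms_fd <- max(diff(cc) / 0.01)
    expect_equal(ms_fd, truth$ms_true[i], tolerance = 1e-3)
    first_nonzero <- tgrid[which(cc > 0)[1]]
    expect_lt(abs(first_nonzero - truth$bat_true[i]), 0.011)
  }
})

test_that("a curve at the published exemplar magnitudes is reproduced", {
  # fast triple-negative-like lesion: MS 0.145 mmol/s, BAT 18.8 s
  truth <- simple_truth(bat = 18.8, ms = 0.145, peak = 36)
  tgrid <- seq(0, 60, by = 0.005)
  cc <- true_concentration_curve(truth, tgrid)
  expect_equal(max(diff(cc) / 0.005), 0.145, tolerance = 1e-3)
  expect_equal(tgrid[which(cc > 0)[1]], 18.8, tolerance = 0.006)
})

test_that("rendered volumes are constant without contrast and noise", {
  p <- default_protocol()
  truth <- data.frame(lesion_size_mm = 8, bat_true = 100, ms_true = 0.01,
                      peak_time_true = 110, washout_rate = 0)
  vol <- render_lesion_volume(truth, p, noise_sigma = 0)  # onset after window
  expect_equal(length(dim(vol$signal)), 4L)
  expect_equal(diff(range(vol$signal)), 0)
  expect_equal(sort(unique(as.vector(vol$mask))), c(0L, 1L))
})

test_that("noiseless voxels round-trip through conversion to the truth", {
  p <- default_protocol()
  truth <- data.frame(lesion_size_mm = 5, bat_true = 20, ms_true = 0.03,
                      peak_time_true = 38, washout_rate = 0.01)
  vol <- render_lesion_volume(truth, p, noise_sigma = 0)
  in_mask <- which(vol$mask != 0)
  nxyz <- prod(dim(vol$mask))
  sig <- vapply(seq_len(p$n_phases),
                function(ti) vol$signal[in_mask + (ti - 1) * nxyz],
                numeric(length(in_mask)))
  conc <- signal_to_concentration(sig, p)
  expected <- true_concentration_curve(truth, vol$times)
  for (v in seq_len(nrow(conc)))
    expect_lt(max(abs(conc[v, ] - expected)), 1e-9)
})

test_that("rendering is bit-identical for a fixed seed", {
  p <- default_protocol()
  truth <- data.frame(lesion_size_mm = 6, bat_true = 20, ms_true = 0.03,
                      peak_time_true = 38, washout_rate = 0.01)
  v1 <- render_lesion_volume(truth, p, noise_sigma = 0.01, seed = 9)
  v2 <- render_lesion_volume(truth, p, noise_sigma = 0.01, seed = 9)
  expect_identical(v1$signal, v2$signal)
  expect_error(render_lesion_volume(truth, p, grid_shape = c(3, 3, 3)),
               "too small")
  expect_error(render_lesion_volume(truth, p, noise_sigma = 0.01),
               "seed")
})

test_that("cohort fixtures on disk are complete and checksum-stable", {
  p <- default_protocol()
  spec <- cohort_spec(n_patients = 2,
                      lesions_per_patient_weights = c(1, 0, 0),
                      noise_sigma = 0.005, seed = 4)
  out1 <- file.path(tempdir(), "fix1")
  out2 <- file.path(tempdir(), "fix2")
  # keep fixture lesions small for speed
  m1 <- write_cohort_fixture(spec, p, out1)
  m2 <- write_cohort_fixture(spec, p, out2)
  expect_equal(nrow(utils::read.csv(file.path(out1, "cohort.csv"))), 2L)
  expect_length(list.files(file.path(out1, "images")), 2L)
  expect_length(list.files(file.path(out1, "masks")), 2L)
  expect_false("ms_true" %in%
                 names(utils::read.csv(file.path(out1, "cohort.csv"))))
  expect_true("ms_true" %in%
                names(utils::read.csv(file.path(out1, "truth", "truth.csv"))))
  expect_equal(m1$md5, m2$md5)   # same seed, identical bytes
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("within-lesion jitter spreads the per-voxel BAT map", {
  p <- default_protocol()
  times <- phase_times(p)
  truth <- data.frame(lesion_size_mm = 10, bat_true = 22, ms_true = 0.04,
                      peak_time_true = 40, washout_rate = 0.01)
  conc <- ufdce:::with_seed(8,
    ufdce:::voxel_concentration_matrix(truth, times, 200, jitter_sd = 0.08,
                                       bat_min = 12))
  lk <- extract_lesion(conc, times)
  bat_v <- attr(conc, "bat_voxel")
  expect_gt(stats::sd(lk$bat_voxel, na.rm = TRUE), 0)
  expect_lt(abs(lk$bat_roi - mean(bat_v)), p$dt)
})
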