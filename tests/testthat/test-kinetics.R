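test_that("peak detection picks the global maximum, first on ties", {
  expect_equal(detect_peak(c(0, 0, 0.1, 0.3, 0.25)), 4L)
  expect_equal(detect_peak(c(0, 0.3, 0.3)), 2L)
  expect_error(detect_peak(rep(0, 5)), "no enhancement")
  expect_error(detect_peak(rep(0.0005, 5)), "no enhancement")
  expect_equal(detect_peak(c(0, NaN, 0.2, 0.1)), 3L)
})

test_that("BAT lands on the last flat sample for an onset at a sample time", {
  p <- acquisition_protocol(dt = 4, n_phases = 15,
                            time_origin = "frame-start")
  times <- phase_times(p)   # 0, 4, ..., 56; onset exactly at t = 20
  conc <- true_concentration_curve(simple_truth(bat = 20, peak = 38), times)
  b <- compute_bat(times, conc)
  expect_true(b$defined)
  expect_equal(b$bat, 20)
})

test_that("degenerate curves give an undefined BAT with a reason", {
  times <- seq(2, 58, by = 4)
  flat <- compute_bat(times, rep(0.5, 15))
  expect_false(flat$defined)           # constant positive: peak at start
  none <- compute_bat(times, rep(0, 15))
  expect_false(none$defined)
  expect_equal(none$reason, "no-enhancement")
  decreasing <- compute_bat(times, seq(0.5, 0.1, length.out = 15))
  expect_false(decreasing$defined)
})

test_that("BAT recovers random noiseless onsets to within one frame", {
  p <- default_protocol()
  times <- phase_times(p)
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    truth <- simple_truth(bat = runif(1, 13, 30),
                          ms = exp(runif(1, log(0.005), log(0.15))),
                          peak = NA)
    truth$peak_time_true <- truth$bat_true + runif(1, 10, 25)
    conc <- true_concentration_curve(truth, times)
    b <- compute_bat(times, conc)
    expect_true(b$defined)
    worst <- max(worst, abs(b$bat - truth$bat_true))
  }
  expect_lte(worst, p$dt)
})

test_that("maximum slope is the steepest adjacent pair inside the window", {
  # linear rise 0 -> 0.3 mmol/l over 20 -> 30 s sampled at 2 s
  times <- seq(0, 40, by = 2)
  conc <- pmin(pmax((times - 20) * 0.03, 0), 0.3)
  b <- compute_bat(times, conc)
  ms <- compute_ms(times, conc, b$bat_index, b$peak_index)
  expect_equal(ms$ms, 0.03, tolerance = 1e-12)
  # piecewise slopes 0.01 / 0.05 / 0.02: brute force over adjacent pairs
  t2 <- 0:9
  seg <- c(0, 0, 0.01, 0.01, 0.05, 0.05, 0.02, 0.02, 0, 0)
  c2 <- cumsum(seg)
  b2 <- list(bat_index = 2L, peak_index = 9L)
  brute <- max(diff(c2[2:9]) / diff(t2[2:9]))
  ms2 <- compute_ms(t2, c2, b2$bat_index, b2$peak_index)
  expect_equal(ms2$ms, brute)
  expect_equal(ms2$ms, 0.05)
  expect_error(compute_ms(t2, c2, 5, 5), "degenerate")
})

test_that("the winning slope pair always lies inside (BAT, peak]", {
  p <- default_protocol()
  times <- phase_times(p)
  set.seed(7)
  for (i in 1:100) {
    truth <- simple_truth(bat = runif(1, 13, 28), ms = runif(1, 0.01, 0.1))
    truth$peak_time_true <- truth$bat_true + runif(1, 8, 25)
    conc <- true_concentration_curve(truth, times) +
      rnorm(length(times), sd = 2e-3)
    b <- compute_bat(times, conc)
    if (!b$defined || b$bat_index >= b$peak_index) next
    ms <- compute_ms(times, conc, b$bat_index, b$peak_index)
    expect_gt(ms$index, b$bat_index)
    expect_lte(ms$index, b$peak_index)
  }
})

test_that("larger true slope gives larger measured slope (order preserved)", {
  p <- default_protocol()
  times <- phase_times(p)
  extract1 <- function(ms) {
    conc <- true_concentration_curve(simple_truth(ms = ms), times)
    b <- compute_bat(times, conc)
    compute_ms(times, conc, b$bat_index, b$peak_index)$ms
  }
  slopes <- vapply(c(0.01, 0.02, 0.04, 0.08, 0.145), extract1, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("vectorized voxel extraction equals the per-curve reference", {
  p <- default_protocol()
  times <- phase_times(p)
  set.seed(3)
  conc <- matrix(rnorm(150 * 15, sd = 0.004), 150, 15)
  base <- true_concentration_curve(simple_truth(), times)
  conc <- conc + matrix(base, 150, 15, byrow = TRUE)
  conc[1, ] <- 0                         # a non-enhancing voxel
  conc[2, 8] <- NaN                      # a flagged sample
  km <- ufdce:::extract_kinetics_matrix(conc, times)
  for (i in seq_len(nrow(conc))) {
    b <- compute_bat(times, conc[i, ])
    expect_identical(km$defined[i], b$defined)
    if (!b$defined) next
    expect_equal(km$bat[i], b$bat)
    expect_equal(km$peak_index[i], b$peak_index)
    if (b$bat_index < b$peak_index) {
      expect_equal(km$ms[i],
                   compute_ms(times, conc[i, ], b$bat_index, b$peak_index)$ms)
    }
  }
})

test_that("ROI aggregation averages voxel BATs and handles invalid voxels", {
  p <- default_protocol()
  times <- phase_times(p)
  c1 <- true_concentration_curve(simple_truth(bat = 18), times)
  c2 <- true_concentration_curve(simple_truth(bat = 22), times)
  lk <- extract_lesion(rbind(c1, c2), times)
  b1 <- compute_bat(times, c1)$bat
  b2 <- compute_bat(times, c2)$bat
  expect_equal(lk$bat_roi, (b1 + b2) / 2)
  expect_equal(lk$n_voxels_valid, 2L)
  # homogeneous lesion: ROI values equal the single-voxel values
  hom <- matrix(c1, nrow = 20, ncol = length(times), byrow = TRUE)
  lkh <- extract_lesion(hom, times)
  lk1 <- extract_lesion(c1, times)
  expect_equal(lkh$bat_roi, lk1$bat_roi)
  expect_equal(lkh$ms_roi, lk1$ms_roi)
  # an invalid voxel is excluded and counted
  lki <- extract_lesion(rbind(c1, 0 * c1), times)
  expect_equal(lki$n_voxels_valid, 1L)
  expect_equal(lki$n_voxels_total, 2L)
  expect_error(extract_lesion(rbind(0 * c1, 0 * c1), times), "no voxel")
})

test_that("ROI BAT is exactly the mean of the valid per-voxel BAT map", {
  p <- default_protocol()
  times <- phase_times(p)
  set.seed(11)
  conc <- t(replicate(40, true_concentration_curve(
    simple_truth(bat = runif(1, 14, 28), ms = runif(1, 0.01, 0.08)), times)))
  conc <- conc + rnorm(length(conc), sd = 1e-3)
  lk <- extract_lesion(conc, times)
  expect_equal(lk$bat_roi, mean(lk$bat_voxel[!is.na(lk$bat_voxel)]))
})

test_that("the two ROI maximum-slope modes agree on homogeneous lesions", {
  p <- default_protocol()
  times <- phase_times(p)
  c1 <- true_concentration_curve(simple_truth(), times)
  hom <- matrix(c1, nrow = 10, ncol = length(times), byrow = TRUE)
  a <- extract_lesion(hom, times, ms_mode = "roi-mean-curve")
  b <- extract_lesion(hom, times, ms_mode = "voxel-mean")
  expect_equal(a$ms_roi, b$ms_roi)
})

test_that("median BAT error degrades monotonically with noise", {
  p <- default_protocol()
  times <- phase_times(p)
  sigmas <- c(0, 0.005, 0.01, 0.02)
  set.seed(202)
  truths <- replicate(80, simple_truth(bat = runif(1, 14, 28),
                                       ms = runif(1, 0.01, 0.08)),
                      simplify = FALSE)
  med_err <- vapply(sigmas, function(sg) {
    errs <- vapply(truths, function(tr) {
      sig <- forward_signal(tr, p)
      if (sg > 0)
        sig <- sig + rnorm(length(sig),
                           sd = sg * spgr_signal(p$t1_pre, p, 500))
      conc <- suppressWarnings(signal_to_concentration(sig, p))
      b <- compute_bat(times, conc)
      if (!b$defined) return(NA_real_)
      abs(b$bat - tr$bat_true)
    }, numeric(1))
    stats::median(errs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_err) >= 0))
})
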