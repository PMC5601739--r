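test_that("moving-average smoothing follows the truncated-window rule", {
  s <- spectrum(1:5, c(0, 0, 10, 0, 0))
  expect_equal(smooth_spectrum(s, 5)$intensity,
               c(10 / 3, 10 / 4, 2, 10 / 4, 10 / 3))
  const <- spectrum(1:11, rep(7, 11))
  expect_equal(smooth_spectrum(const, 5)$intensity, rep(7, 11))
  expect_equal(smooth_spectrum(s, 1)$intensity, s$intensity)
  expect_error(smooth_spectrum(s, 4), "odd")
  expect_error(smooth_spectrum(s, 0), "odd")
})

test_that("smoothing is linear in the intensities", {
  set.seed(1)
  mz <- 1:50
  x <- runif(50); y <- runif(50)
  a <- 2.5; b <- -1.2
  lhs <- smooth_spectrum(spectrum(mz, a * x + b * y), 7)$intensity
  rhs <- a * smooth_spectrum(spectrum(mz, x), 7)$intensity +
    b * smooth_spectrum(spectrum(mz, y), 7)$intensity
  expect_equal(lhs, rhs)
})

test_that("baseline estimation tracks flat, impulse and ramp backgrounds", {
  flat <- spectrum(seq(1000, 2000), rep(3, 1001))
  expect_equal(estimate_baseline(flat, 100), rep(3, 1001))

  imp <- spectrum(seq(1000, 2000), c(rep(0, 500), 80, rep(0, 500)))
  expect_equal(estimate_baseline(imp, 100), rep(0, 1001))

  # two Gaussian peaks on a linear ramp: anchors must sit on the ramp
  ramp_slope <- 0.01
  s <- gaussian_spectrum(mz = seq(1000, 2000, by = 1),
                         centers = c(1300, 1700), heights = c(100, 120),
                         sigmas = c(3, 3), ramp = c(5, ramp_slope))
  base <- estimate_baseline(s, 100)
  ramp <- 5 + ramp_slope * (s$mz - 1000)
  valley <- s$mz > 1400 & s$mz < 1600
  expect_lt(max(abs(base[valley] - ramp[valley])), 100 / 100)
  expect_true(all(base <= max(s$intensity)))
  expect_warning(estimate_baseline(spectrum(1:20, rnorm(20)), 100), "span")
})

test_that("baseline subtraction clamps at zero and validates lengths", {
  s <- spectrum(1:3, c(5, 7, 2))
  expect_equal(subtract_baseline(s, s$intensity)$intensity, c(0, 0, 0))
  expect_equal(subtract_baseline(s, rep(0, 3))$intensity, s$intensity)
  expect_equal(subtract_baseline(s, c(7, 7, 7))$intensity, c(0, 0, 0))
  expect_error(subtract_baseline(s, 1:2), "length")
})

test_that("the local MAD noise estimator is calibrated and scale-equivariant", {
  set.seed(7)
  noise <- rnorm(9001)
  s1 <- spectrum(seq(1000, 10000), noise)
  lev1 <- estimate_noise(s1, 100)
  expect_gt(median(lev1), 0.9)
  expect_lt(median(lev1), 1.1)

  s2 <- spectrum(seq(1000, 10000), 2 * noise)
  lev2 <- estimate_noise(s2, 100)
  expect_equal(lev2, 2 * lev1, tolerance = 1e-10)

  expect_warning(lev0 <- estimate_noise(spectrum(1:100, rep(0, 100)), 10),
                 "identical")
  expect_equal(lev0, rep(0, 100))
})

test_that("peak detection applies the S/N cut-off inclusively with accurate centroids", {
  flat <- spectrum(1:100, rep(1, 100))
  expect_equal(nrow(detect_peaks(flat, rep(1, 100), 5)), 0)

  s <- gaussian_spectrum(mz = seq(1000, 1100, by = 1), centers = 1050,
                         heights = 10, sigmas = 3)
  pk <- detect_peaks(s, rep(1, 101), 5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$snr, 10)
  expect_lt(abs(pk$mz - 1050), 0.5)

  mk <- function(h) {
    y <- rep(0, 21); y[11] <- h
    spectrum(1:21, y)
  }
  expect_equal(nrow(detect_peaks(mk(5), rep(1, 21), 5)), 1)   # S/N exactly 5
  expect_equal(nrow(detect_peaks(mk(4.99), rep(1, 21), 5)), 0)
})

test_that("plateaus resolve to their leftmost point and zero noise gives infinite S/N", {
  y <- c(0, 1, 3, 3, 3, 1, 0)
  s <- spectrum(1:7, y)
  pk <- detect_peaks(s, rep(1, 7), 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$intensity, 3)
  pk0 <- detect_peaks(s, rep(0, 7), 5)
  expect_equal(pk0$snr, Inf)
})

test_that("raising the S/N cut-off never adds a peak", {
  set.seed(21)
  for (rep_i in 1:5) {
    s <- gaussian_spectrum(mz = seq(1000, 2000, by = 1),
                           centers = sample(1050:1950, 8),
                           heights = runif(8, 2, 50),
                           sigmas = rep(2, 8), noise_sd = 1)
    s <- smooth_spectrum(s, 5)
    noise <- estimate_noise(s, 100)
    lo <- detect_peaks(s, noise, 3)
    hi <- detect_peaks(s, noise, 8)
    expect_true(all(hi$mz %in% lo$mz))
    expect_true(all(lo[lo$mz %in% hi$mz, "snr"] >= 3))
  }
})

test_that("TIC normalization sums to one, preserves proportions and is idempotent", {
  s <- spectrum(1:2, c(1, 3))
  n1 <- normalize_tic(s)
  expect_equal(n1$intensity, c(0.25, 0.75))
  set.seed(5)
  r <- spectrum(1:200, runif(200, 0, 50))
  nr <- normalize_tic(r)
  expect_equal(sum(nr$intensity), 1, tolerance = 1e-12)
  expect_equal(normalize_tic(nr)$intensity, nr$intensity)
  expect_error(normalize_tic(spectrum(1:3, c(0, 0, 0))), "positive")
})

test_that("the composed chain is pure and detects a planted noiseless peak", {
  spec <- peak_spec(2000, 800, 800, cv = 1e-9, presence_case = 1,
                    presence_control = 1, width_sigma = 1)
  cfg <- cohort_config(n_cases = 1, n_controls = 0, mz_min = 1000,
                       mz_max = 3000, peak_specs = spec,
                       baseline_amplitude = 50, noise_sd = 0,
                       tic_variation_cv = 0, mz_jitter_max_rel = 0, seed = 2)
  s <- generate_cohort(cfg)$spectra[[1]]
  out1 <- preprocess_spectrum(s, preprocess_params(mz_min = 1000, mz_max = 3000))
  out2 <- preprocess_spectrum(s, preprocess_params(mz_min = 1000, mz_max = 3000))
  expect_identical(out1, out2)
  expect_equal(nrow(out1$peaks), 1)
  expect_lt(abs(out1$peaks$mz - 2000), 1)
  expect_equal(sum(out1$spectrum$intensity), 1, tolerance = 1e-12)
  expect_true(all(c("smooth(window=5)", "subtract_baseline", "normalize_tic")
                  %in% out1$spectrum$processing_log))
})

test_that("planted peaks at high S/N are recalled with sub-grid centroid accuracy", {
  specs <- do.call(rbind, lapply(seq(1500, 4200, by = 300), function(m) {
    peak_spec(m, 1500, 1500, cv = 0.1, presence_case = 1,
              presence_control = 1)
  }))
  cfg <- cohort_config(n_cases = 10, n_controls = 0, mz_max = 4500,
                       peak_specs = specs, noise_sd = 10,
                       tic_variation_cv = 0, mz_jitter_max_rel = 0, seed = 9)
  set <- generate_cohort(cfg)
  params <- preprocess_params(mz_max = 4500)
  hits <- 0; total <- 0; cent_err <- numeric()
  for (s in set$spectra) {
    pk <- preprocess_spectrum(s, params)$peaks
    for (m in specs$mz_center) {
      total <- total + 1
      d <- abs(pk$mz - m)
      if (any(d < 3)) {
        hits <- hits + 1
        cent_err <- c(cent_err, min(d))
      }
    }
  }
  expect_gte(hits / total, 0.95)
  expect_true(all(cent_err <= 1))  # within one grid step
})
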