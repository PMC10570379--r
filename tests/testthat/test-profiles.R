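test_that("line profiles are exact on constant and affine intensity fields", {
  g <- pixel_geometry(0.1)
  const <- matrix(7, 40, 40)
  p <- extract_line_profile(const, c(1, 0.5), c(3, 3), geometry = g,
                            averaging_width = 3)
  expect_true(all(p$values == 7))
  expect_error(extract_line_profile(const, c(1, 1), c(1, 1), geometry = g),
               "coincide")
  expect_error(extract_line_profile(const, c(1, 1), c(1, 100), geometry = g),
               "exits")
  # I(y, x) = x + 2 y (um units); bilinear interpolation reproduces it exactly
  aff <- outer(0:39, 0:39, function(i, j) j * 0.1 + 2 * i * 0.1)
  p2 <- extract_line_profile(aff, c(0.35, 0.2), c(2.75, 3.4), geometry = g)
  u <- (c(2.75, 3.4) - c(0.35, 0.2)) / sqrt(sum((c(2.75, 3.4) - c(0.35, 0.2))^2))
  expected <- (0.2 + p2$positions * u[2]) + 2 * (0.35 + p2$positions * u[1])
  expect_equal(p2$values, expected, tolerance = 1e-12)
})

test_that("45-degree profiles match a brute-force bilinear oracle", {
  set.seed(11)
  g <- pixel_geometry(0.1)
  img <- matrix(runif(900), 30, 30)
  p <- extract_line_profile(img, c(0.4, 0.3), c(2.0, 1.9), geometry = g)
  # independent per-sample oracle
  oracle <- vapply(p$positions, function(s) {
    y <- (0.4 + s / sqrt(2)) / 0.1; x <- (0.3 + s / sqrt(2)) / 0.1
    i0 <- floor(y); j0 <- floor(x); fy <- y - i0; fx <- x - j0
    (1 - fy) * ((1 - fx) * img[i0 + 1, j0 + 1] + fx * img[i0 + 1, j0 + 2]) +
      fy * ((1 - fx) * img[i0 + 2, j0 + 1] + fx * img[i0 + 2, j0 + 2])
  }, 0)
  expect_equal(p$values, oracle, tolerance = 1e-12)
})

test_that("Gaussian fitting recovers FWHM, polarity and handles noise", {
  x <- seq(0, 10, by = 0.05)
  fit <- fit_gaussian_fwhm(gauss_profile(x, 2, 5, 1, baseline = 0))
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(fit$fwhm / fit$sigma, 2.3548, tolerance = 1e-4)
  expect_true(fit$converged)
  # trough: same width, negative amplitude, one code path
  tr <- gauss_profile(x, -2, 5, 1, baseline = 3)
  fit2 <- fit_gaussian_fwhm(tr)
  expect_equal(fit2$fwhm, fit$fwhm, tolerance = 1e-6)
  expect_lt(fit2$amplitude, 0)
  # 2% amplitude noise: fwhm within 3% of 1.1774 um
  withr::with_seed(11, {
    pr <- gauss_profile(x, 1, 5, 0.5)
    pr$values <- pr$values + rnorm(length(x), 0, 0.02)
    fit3 <- fit_gaussian_fwhm(pr, "peak")
    expect_lt(abs(fit3$fwhm - 1.1774) / 1.1774, 0.03)
  })
  expect_error(fit_gaussian_fwhm(gauss_profile(x, 0, 5, 1, baseline = 2)),
               "constant")
  expect_error(fit_gaussian_fwhm(gauss_profile(x[1:5], 1, 1, 1)), "7 samples")
})

test_that("noiseless fits recover FWHM within 0.1% across two decades of width", {
  for (sigma in c(0.2, 0.5, 1, 2.5, 5, 10)) {
    x <- seq(-6 * sigma, 6 * sigma, length.out = 301)
    fit <- fit_gaussian_fwhm(gauss_profile(x, 1.5, 0, sigma, baseline = 0.2),
                             "peak")
    expect_lt(abs(fit$fwhm - 2.3548 * sigma) / (2.3548 * sigma), 0.001)
  }
})

test_that("bead resolution excludes crowded pairs and survives empty fields", {
  g <- pixel_geometry(0.04)
  blank <- image_stack(matrix(0.01, 64, 64), g)
  expect_equal(nrow(measure_bead_resolution(blank)), 0)
  # two isolated beads and one close pair
  sig <- 0.212 / 2.3548 / 0.04
  img <- matrix(0.01, 128, 128)
  put <- function(img, cy, cx) {
    gy <- exp(-((0:127) - cy)^2 / (2 * sig^2))
    img + outer(gy, exp(-((0:127) - cx)^2 / (2 * sig^2)))
  }
  img <- put(put(img, 30, 30), 30, 100)
  img <- put(put(img, 95, 40), 95, 40 + 2.2 * 0.212 / 0.04)  # pair < 3 FWHM apart
  st <- image_stack(img, g)
  res <- measure_bead_resolution(st, detect_threshold = 0.4)
  expect_gte(sum(res$crowded), 2)
  expect_equal(attr(res, "n_used"), nrow(res) - sum(res$crowded))
  expect_equal(attr(res, "mean_fwhm_um"), 0.212, tolerance = 0.02)
})

test_that("SNR time course is flat for stationary series and scales with contrast", {
  g <- pixel_geometry(0.1, dt = 5)
  # flat background on the left; a sine stripe under the measured line
  base <- matrix(0.5, 32, 32)
  base[, 13:32] <- 0.5 + 0.2 * rep(sin((13:32) / 3), each = 32)
  arr <- array(0, dim = c(6, 1, 1, 32, 32))
  for (t in 1:6) arr[t, 1, 1, , ] <- base
  arr[4, 1, 1, , ] <- 0.5 + 2 * (base - 0.5)   # doubled contrast at frame 4
  noise <- matrix(rnorm(32 * 32, 0, 0.01), 32)  # same bg noise every frame
  for (t in 1:6) arr[t, 1, 1, , ] <- pmax(arr[t, 1, 1, , ] + noise, 0)
  st <- image_stack(arr, g)
  bg <- matrix(FALSE, 32, 32); bg[1:8, 1:8] <- TRUE   # structure-free corner
  out <- snr_timecourse(st, c(1.5, 1.3), c(1.5, 3.0), roi_mask(bg),
                        averaging_width = 1)
  expect_equal(out$snr[4] / out$snr[1], 2, tolerance = 0.15)
  flat <- out$snr[-4]
  expect_lt(diff(range(flat)) / mean(flat), 0.05)
})

test_that("dF/F and intensity drop follow their defining formulas", {
  expect_true(all(delta_f_over_f(rep(3, 10), 4) == 0))
  tr <- c(rep(2, 5), 4, 2, 2)
  expect_equal(delta_f_over_f(tr, 5)[6], 1.0)
  ramp <- seq(10, 29, by = 1)
  out <- delta_f_over_f(ramp, 10)
  f0 <- mean(ramp[1:10])
  expect_equal(out, (ramp - f0) / f0, tolerance = 1e-12)
  expect_error(delta_f_over_f(ramp, 0), "baseline_frames")
  expect_error(delta_f_over_f(c(0, 0, 1, 2), 2), "F0")

  s <- data.frame(time_h = 0:5, intensity = 100 * exp(-log(2) * (0:5)))
  expect_equal(intensity_drop(s, 0, 1), 50, tolerance = 1e-9)
  expect_equal(intensity_drop(data.frame(time_h = 0:5, intensity = rep(4, 6)),
                              1, 4), 0)
  # invariant to positive rescaling
  s2 <- s; s2$intensity <- s2$intensity * 17
  expect_equal(intensity_drop(s, 0.5, 3.5), intensity_drop(s2, 0.5, 3.5))
  expect_error(intensity_drop(s, 3, 1))
  expect_error(intensity_drop(s, -1, 3), "range")
})
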