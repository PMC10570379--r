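test_that("blur and noise model: identity, mean conservation, determinism", {
  set.seed(2)
  g <- pixel_geometry(0.1)
  st <- image_stack(matrix(runif(64 * 64), 64), g)
  # zero PSF, zero noise is the identity
  out <- apply_psf_noise(st, 0, list(photon_peak = 0, read_sigma = 0))
  expect_equal(out$data, st$data)
  # unit-sum kernel with circular boundary conserves the mean to 1e-9
  bl <- apply_psf_noise(st, 0.5, list(photon_peak = 0, read_sigma = 0))
  expect_lt(abs(mean(bl$data) - mean(st$data)), 1e-9)
  # seeded noise is reproducible
  n1 <- apply_psf_noise(st, 0.3, list(photon_peak = 100, read_sigma = 0.01), seed = 9)
  n2 <- apply_psf_noise(st, 0.3, list(photon_peak = 100, read_sigma = 0.01), seed = 9)
  expect_identical(n1$data, n2$data)
})

test_that("blurring a Gaussian stripe obeys the FWHM quadrature rule", {
  g <- pixel_geometry(0.04)
  x_um <- (0:399) * 0.04
  for (ab in list(c(0.3, 0.4), c(0.5, 0.2))) {
    a <- ab[1]; b <- ab[2]
    stripe <- matrix(rep(exp(-(x_um - 8)^2 / (2 * (a / 2.3548)^2)), 200),
                     400, 200)       # varies along rows (y), constant in x
    st <- image_stack(stripe, g)
    bl <- apply_psf_noise(st, b, list(photon_peak = 0, read_sigma = 0))
    prof <- extract_line_profile(bl, c(0.2, 4), c(15.8, 4), geometry = g)
    fit <- fit_gaussian_fwhm(prof, "peak")
    expect_lt(abs(fit$fwhm - sqrt(a^2 + b^2)) / sqrt(a^2 + b^2), 0.02)
  }
})

test_that("neuropil phantom hits the target ECS fraction and keeps a pure plateau", {
  cfg <- phantom_config(seed = 1, ny = 256L, nx = 256L,
                        noise = list(photon_peak = 0, read_sigma = 0))
  ph <- make_neuropil_phantom(cfg)
  expect_lt(abs(ph$truth$vf_achieved - 0.23), 0.002 + 1e-12)
  expect_true(abs(mean(ph$truth$ecs_mask$mask) - 0.23) < 0.05)
  pl <- ph$truth$plateau
  plateau_px <- get_frame(ph$stack)[(pl[1] + 5):(pl[3] - 3), (pl[2] + 5):(pl[4] - 3)]
  expect_true(all(plateau_px > 0.99))
  # near-unity target: almost no cells
  cfg2 <- phantom_config(seed = 1, ny = 128L, nx = 128L, vf_true = 0.995,
                         noise = list(photon_peak = 0, read_sigma = 0))
  ph2 <- make_neuropil_phantom(cfg2)
  expect_gt(mean(get_frame(ph2$stack)), 0.99)
  # determinism
  ph3 <- make_neuropil_phantom(cfg)
  expect_identical(ph3$stack$data, ph$stack$data)
  expect_identical(ph3$truth$ecs_mask$mask, ph$truth$ecs_mask$mask)
})

test_that("vessel phantom cross-sections carry the configured widths", {
  cfg <- phantom_config(seed = 3, vessel = list(n_vessels = 6L),
                        noise = list(photon_peak = 0, read_sigma = 0))
  ph <- make_vessel_phantom(cfg)
  tr <- ph$truth$vessels
  m <- measure_vessels(ph$stack, ph$truth$axes, frames = tr$frame)
  expect_true(all(m$quality == "ok"))
  vid <- as.integer(sub("v", "", m$vessel_label))
  expect_lt(max(abs(m$lumen_fwhm_um - tr$lumen_fwhm_um[vid]) /
                tr$lumen_fwhm_um[vid]), 0.02)
  pvs <- rowMeans(cbind(m$pvs_fwhm_left_um, m$pvs_fwhm_right_um), na.rm = TRUE)
  expect_lt(max(abs(pvs - tr$pvs_fwhm_um[vid]) / tr$pvs_fwhm_um[vid]), 0.05)
})

test_that("vessel coupling: zero noise is collinear; sample r matches closed form", {
  cfg0 <- phantom_config(seed = 5,
                         vessel = list(n_vessels = 40L, coupling_noise_sigma = 0))
  tr0 <- make_vessel_phantom(cfg0)$truth$vessels
  free <- tr0$pvs_fwhm_um > 0.2 + 1e-9     # exclude floor-clipped widths
  expect_gt(sum(free), 30)
  expect_equal(cor(tr0$lumen_fwhm_um[free], tr0$pvs_fwhm_um[free]), 1,
               tolerance = 1e-12)
  cfg <- phantom_config(seed = 6, vessel = list(n_vessels = 500L))
  tr <- make_vessel_phantom(cfg)$truth$vessels
  v <- cfg$vessel
  r_pop <- v$coupling_slope * v$lumen_sd_um /
    sqrt((v$coupling_slope * v$lumen_sd_um)^2 + v$coupling_noise_sigma^2)
  expect_lt(abs(cor(tr$lumen_fwhm_um, tr$pvs_fwhm_um) - r_pop), 0.03)
})

test_that("lesion phantom honours class probabilities and the empty-field limit", {
  cfg <- small_lesion_config(seed = 2, n_cups = 0L)
  ph <- make_lesion_series(cfg)
  egfp <- image_stack(ph$stack$data[, 1, , , , drop = FALSE], ph$stack$geometry)
  det <- detect_phagocytic_cups(egfp)
  expect_equal(nrow(det$cups), 0)
  cfg1 <- small_lesion_config(seed = 2, n_cups = 8L,
                              content_probs = c(lysed = 1, intact = 0, both = 0))
  expect_true(all(make_lesion_series(cfg1)$truth$cups$class == "lysed"))
  # exact-counts mode yields the rounded integer split
  cfg2 <- phantom_config(seed = 3, lesion = list(exact_counts = TRUE))
  cls <- make_lesion_series(cfg2)$truth$cups$class
  expect_equal(as.vector(table(cls)[c("lysed", "intact", "both")]),
               c(82L, 40L, 8L))
})

test_that("trajectory generator arithmetic is exact without jitter", {
  cfg <- phantom_config(seed = 5, trajectories = list(
    classes = list(test = list(n = 3L, speed_um_s = 0.1, path_length_um = 12)),
    jitter_sigma_um = 0, dt_s = 20))
  tr <- make_trajectories(cfg)
  t1 <- tr$table[tr$table$tip_id == 1, ]
  steps <- sqrt(diff(t1$y_um)^2 + diff(t1$x_um)^2)
  # constant nominal speed: 2 um per frame until the truncated arrival step
  expect_equal(steps[1:5], rep(2, 5), tolerance = 1e-12)
  tru <- tr$truth[tr$truth$tip_id == 1, ]
  m <- track_metrics(t1, c(tru$lesion_y_um, tru$lesion_x_um), 20)
  expect_equal(m$cumulative_distance_um, 12, tolerance = 1e-9)
  # neuropil-class values: 17.1 um at 0.07 um/s
  cfg2 <- phantom_config(seed = 5, trajectories = list(jitter_sigma_um = 0))
  tr2 <- make_trajectories(cfg2)
  mot <- cohort_motility(tr2$table, tr2$truth, dt_s = 20)
  np <- mot[mot$class == "neuropil", ]
  expect_equal(mean(np$cumulative_distance_um), 17.1, tolerance = 1e-9)
  expect_equal(mean(np$mean_velocity_um_s), 0.07, tolerance = 1e-9)
})

test_that("jittered cohorts recover nominal speed within 3 SEM", {
  cfg <- phantom_config(seed = 8)
  tr <- make_trajectories(cfg)
  mot <- cohort_motility(tr$table, tr$truth, dt_s = 20)
  np <- mot[mot$class == "neuropil", ]
  sem <- sd(np$mean_velocity_um_s) / sqrt(nrow(np))
  expect_lt(abs(mean(np$mean_velocity_um_s) - 0.07), 3 * sem + 0.002)
})

test_that("clearance series closed forms hold", {
  s <- make_clearance_series(phantom_config())
  i <- function(t) approx(s$time_h, s$intensity, t)$y
  expect_equal(i(4) / i(1), 1 - 0.475, tolerance = 1e-12)
  s0 <- make_clearance_series(phantom_config(clearance = list(lambda_per_h = 0)))
  expect_true(all(s0$intensity == s0$intensity[1]))
  sh <- make_clearance_series(phantom_config(clearance = list(lambda_per_h = log(2))))
  expect_equal(approx(sh$time_h, sh$intensity, 2)$y /
                 approx(sh$time_h, sh$intensity, 1)$y, 0.5, tolerance = 1e-12)
})

test_that("bead fields are seeded, separated, and sized as configured", {
  cfg <- phantom_config(seed = 7, noise = list(photon_peak = 0, read_sigma = 0))
  bf <- make_bead_field(cfg)
  # noiseless spot has the configured image-domain FWHM (5.3 px at 40 nm)
  p1 <- bf$truth[1, ]
  dx <- 0.04
  iy <- round(p1$y_um / dx) + 1
  prof <- list(positions = (-10:10) * dx,
               values = get_frame(bf$stack)[iy, round(p1$x_um / dx) + 1 + (-10:10)])
  fit <- fit_gaussian_fwhm(prof, "peak")
  expect_equal(fit$fwhm, 0.212, tolerance = 0.01)
  # spots are separated
  d <- as.matrix(dist(bf$truth[, c("y_um", "x_um")])); diag(d) <- Inf
  expect_gt(min(d), 3 * 0.212)
  # different seeds give different positions; zero count gives a blank field
  bf2 <- make_bead_field(phantom_config(seed = 8,
                                        noise = list(photon_peak = 0, read_sigma = 0)))
  expect_false(isTRUE(all.equal(bf$truth$y_um, bf2$truth$y_um)))
  bf0 <- make_bead_field(phantom_config(seed = 7, beads = list(n = 0L),
                                        noise = list(photon_peak = 0, read_sigma = 0)))
  expect_equal(nrow(bf0$truth), 0)
  expect_lt(diff(range(bf0$stack$data)), 1e-12)
})
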