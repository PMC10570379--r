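test_that("disk median filter matches a per-pixel sort oracle", {
  set.seed(13)
  fr <- matrix(runif(256), 16, 16)
  out <- shadowimg:::median_filter_disk_cpp(fr, 2L)
  # brute-force oracle: shrinking disk neighbourhood + stats::median
  offs <- expand.grid(a = -2:2, b = -2:2)
  offs <- offs[offs$a^2 + offs$b^2 <= 4, ]
  oracle <- fr
  for (i in 1:16) for (j in 1:16) {
    ii <- i + offs$a; jj <- j + offs$b
    keep <- ii >= 1 & ii <= 16 & jj >= 1 & jj <= 16
    oracle[i, j] <- median(fr[cbind(ii[keep], jj[keep])])
  }
  expect_equal(out, oracle, tolerance = 1e-15)
  # a single salt pixel in a constant frame disappears
  cst <- matrix(0.4, 20, 20); cst[10, 10] <- 1
  filt <- shadowimg:::median_filter_disk_cpp(cst, 4L)
  expect_true(all(filt == 0.4))
})

test_that("preprocessing yields a normalized inverted stack", {
  set.seed(3)
  g <- pixel_geometry(0.1)
  st <- image_stack(array(runif(2 * 32 * 32) * 9, dim = c(2, 32, 32)),
                    pixel_geometry(0.1, dt = 20), axes = "tyx")
  inv <- preprocess_coshi(st, triage_params(median_radius = 2))
  expect_true(inv$normalized)
  expect_gte(min(inv$data), 0)
  expect_lte(max(inv$data), 1)
})

test_that("tissue-state thresholds follow strict inequalities and stay disjoint", {
  g <- pixel_geometry(0.1)
  fr <- matrix(0.5, 4, 4)
  fr[1, 1] <- 0.0; fr[1, 2] <- 0.01; fr[2, 2] <- 0.8
  st <- image_stack(array(fr, dim = c(1, 1, 1, 4, 4)), g, normalized = TRUE)
  masks <- threshold_tissue_state(st)
  expect_equal(sum(masks$lysed), 2)   # 0.0 and 0.01
  expect_equal(sum(masks$intact), 1)  # 0.8
  expect_false(any(masks$intact & masks$lysed))
  # all-mid frame: both empty
  mid <- image_stack(array(0.5, dim = c(1, 1, 1, 4, 4)), g, normalized = TRUE)
  mm <- threshold_tissue_state(mid)
  expect_false(any(mm$intact) || any(mm$lysed))
  # degenerate thresholds 0/1 with strict inequalities select nothing
  mm2 <- threshold_tissue_state(st, triage_params(intact_threshold = 1,
                                                  lysed_threshold = 0))
  expect_false(any(mm2$intact) || any(mm2$lysed))
  # property: disjoint for random stacks
  set.seed(5)
  for (k in 1:5) {
    rs <- image_stack(array(runif(2 * 16 * 16), dim = c(2, 1, 1, 16, 16)), g,
                      normalized = TRUE)
    mk <- threshold_tissue_state(rs)
    expect_false(any(mk$intact & mk$lysed))
  }
})

test_that("lesion ROI covers newly lysed material", {
  g <- pixel_geometry(0.1)
  ny <- 64
  intact <- array(FALSE, dim = c(ny, ny, 3))
  lysed <- array(FALSE, dim = c(ny, ny, 3))
  # nothing at baseline; a lysed disk appears at frame 2
  dl <- disk_mask(ny, ny, 31, 31, 8)
  lysed[, , 2] <- dl; lysed[, , 3] <- dl
  roi <- detect_lesion_roi(list(intact = intact, lysed = lysed),
                           baseline_frames = 1, close_radius_px = 3)
  expect_false(any(roi[, , 1]))
  expect_true(all(roi[, , 2][dl]))
  expect_true(all(roi[, , 3][dl]))
})

test_that("fill-holes subtraction equals the flood-fill-from-border oracle", {
  set.seed(17)
  g <- pixel_geometry(0.5)
  for (k in 1:25) {
    bin <- matrix(runif(64 * 64) < 0.45, 64, 64)
    st <- image_stack(array(bin * 1.0, dim = c(1, 1, 1, 64, 64)), g)
    det <- detect_phagocytic_cups(st, binarize = 0.5)
    expect_identical(det$holes[, , 1], flood_fill_holes_oracle(bin))
  }
})

test_that("cup detection keeps closed annuli and rejects open or solid shapes", {
  g <- pixel_geometry(0.16)
  ny <- 128
  img <- matrix(0.05, ny, ny)
  img[disk_mask(ny, ny, 24, 24, 12)] <- 1                 # solid disk: no hole
  ring <- annulus_mask(ny, ny, 64, 64, 18.75, 24)         # 6 um interior
  img[ring] <- 1
  cshape <- annulus_mask(ny, ny, 100, 40, 12, 17)
  cshape[96:104, 40:60] <- FALSE                          # opened ring
  img[cshape] <- 1
  st <- image_stack(array(img, dim = c(1, 1, 1, ny, ny)), g)
  det <- detect_phagocytic_cups(st, binarize = 0.5)
  expect_equal(length(unique(det$cups$cup_id)), 1)
  expect_equal(det$cups$eq_diam_um, 6, tolerance = 0.1)
  expect_gt(det$cups$circularity, 0.9)
})

test_that("cup detection is translation-equivariant", {
  g <- pixel_geometry(0.16)
  ny <- 96
  img <- matrix(0.05, ny, ny)
  img[annulus_mask(ny, ny, 40, 44, 15, 20)] <- 1
  st1 <- image_stack(array(img, dim = c(1, 1, 1, ny, ny)), g)
  sh <- matrix(0.05, ny, ny)
  sh[11:ny, 6:ny] <- img[1:(ny - 10), 1:(ny - 5)]          # shift by (10, 5) px
  st2 <- image_stack(array(sh, dim = c(1, 1, 1, ny, ny)), g)
  d1 <- detect_phagocytic_cups(st1, binarize = 0.5)$cups
  d2 <- detect_phagocytic_cups(st2, binarize = 0.5)$cups
  expect_equal(d2$y_um - d1$y_um, 10 * 0.16, tolerance = 1e-9)
  expect_equal(d2$x_um - d1$x_um, 5 * 0.16, tolerance = 1e-9)
  expect_equal(d2$area_um2, d1$area_um2)
})

test_that("content classification follows the median (majority) rule", {
  g <- pixel_geometry(0.16)
  ny <- 96
  img <- matrix(0.05, ny, ny)
  interior <- disk_mask(ny, ny, 48, 48, 15)
  img[annulus_mask(ny, ny, 48, 48, 15, 20)] <- 1
  st <- image_stack(array(img, dim = c(1, 1, 1, ny, ny)), g)
  det <- detect_phagocytic_cups(st, binarize = 0.5)
  expect_equal(length(unique(det$cups$cup_id)), 1)
  mk_masks <- function(lys_frac, int_frac) {
    lys <- array(FALSE, dim = c(ny, ny, 1)); int <- array(FALSE, dim = c(ny, ny, 1))
    pix <- which(interior)
    n <- length(pix)
    lys[, , 1][pix[seq_len(floor(lys_frac * n))]] <- TRUE
    int[, , 1][pix[(floor(lys_frac * n) + 1):(floor((lys_frac + int_frac) * n))]] <- TRUE
    list(intact = int, lysed = lys)
  }
  # interior 100% lysed -> lysed
  cls <- classify_cup_contents(det, mk_masks(1, 0))
  expect_equal(cls$cups$class, "lysed")
  # 40% lysed / 40% intact / 20% neither -> neither median non-zero -> empty
  cls2 <- classify_cup_contents(det, mk_masks(0.4, 0.4))
  expect_equal(cls2$cups$class, "empty")
  # 60% intact -> intact
  cls3 <- classify_cup_contents(det, mk_masks(0.0, 0.6))
  expect_equal(cls3$cups$class, "intact")
  expect_equal(sum(cls3$summary$percent), 100, tolerance = 0.1)
})

test_that("enrichment compares lesion-area fractions with cup positivity", {
  ny <- 64
  lys <- array(FALSE, dim = c(ny, ny, 1)); int <- array(FALSE, dim = c(ny, ny, 1))
  roi <- array(FALSE, dim = c(ny, ny, 1))
  roi[, , 1][1:32, ] <- TRUE
  lys[, , 1][1:16, ] <- TRUE       # half the ROI lysed
  int[, , 1][17:32, ] <- TRUE      # other half intact
  masks <- list(intact = int, lysed = lys)
  pf <- data.frame(cup_id = 1:4, frame = 1,
                   pos_lysed = c(TRUE, TRUE, TRUE, TRUE),
                   pos_intact = rep(FALSE, 4))
  cls <- list(per_frame = pf)
  enr <- enrichment_stats(masks, roi, cls)
  expect_equal(unname(enr$in_roi["lysed"]), 50)
  expect_equal(unname(enr$in_roi["intact"]), 50)
  expect_equal(unname(enr$in_pc["lysed"]), 100)
  expect_equal(unname(enr$in_pc["intact"]), 0)
})

test_that("track metrics: straight-path arithmetic, stationary and short inputs", {
  traj <- data.frame(frame = 1:15, y_um = 0, x_um = (0:14) * 0.1)
  m <- track_metrics(traj, lesion_point = c(0, 1.4), dt_s = 20,
                     arrival_radius_um = 0.05)
  expect_equal(m$mean_velocity_um_s, 0.1 / 20)
  expect_equal(m$arrival_frame, 15L)
  expect_equal(m$cumulative_distance_um, 1.4, tolerance = 1e-12)
  stat <- data.frame(frame = 1:10, y_um = 5, x_um = 5)
  ms <- track_metrics(stat, c(50, 50), 20)
  expect_equal(ms$mean_velocity_um_s, 0)
  expect_false(ms$arrived)
  expect_error(track_metrics(traj[1:6, ], c(0, 1), 20), "8 frames")
})

test_that("path classification detects impeding cell bodies on the segment", {
  g <- pixel_geometry(0.16)
  ny <- 256
  empty <- matrix(0.1, ny, ny)
  traj <- data.frame(frame = 1:8, y_um = 20, x_um = 2)
  lesion <- c(20, 38)
  expect_equal(classify_path(traj, lesion, empty, g), "neuropil")
  # 8 um dark disk centred on the segment (inverted intensity > 0.7)
  body <- empty; body[disk_mask(ny, ny, 20 / 0.16, 20 / 0.16, 4 / 0.16)] <- 0.95
  expect_equal(classify_path(traj, lesion, body, g), "cell_bodies")
  # same disk offset 10 um perpendicular: path is clear
  off <- empty; off[disk_mask(ny, ny, 30 / 0.16, 20 / 0.16, 4 / 0.16)] <- 0.95
  expect_equal(classify_path(traj, lesion, off, g), "neuropil")
})

test_that("small lesion phantom round-trips classes through the full pipeline", {
  cfg <- small_lesion_config(seed = 6, n_cups = 9L)
  ph <- make_lesion_series(cfg)
  egfp <- image_stack(ph$stack$data[, 1, , , , drop = FALSE], ph$stack$geometry)
  shadow <- image_stack(ph$stack$data[, 2, , , , drop = FALSE], ph$stack$geometry)
  masks <- threshold_tissue_state(preprocess_coshi(shadow))
  det <- detect_phagocytic_cups(egfp)
  cls <- classify_cup_contents(det, masks)
  expect_equal(cls$summary$n_cups, 9)
  truth_tab <- table(factor(ph$truth$cups$class,
                            levels = c("lysed", "intact", "both", "empty")))
  expect_equal(unname(cls$summary$counts), as.vector(truth_tab))
})
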