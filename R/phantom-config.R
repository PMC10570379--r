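#' Configuration for the shadow-image phantom generators
#'
#' One seeded configuration object drives every synthetic-data generator.
#' Defaults reproduce the study conditions of in vivo two-photon shadow
#' imaging of mouse cortex: 0.16 um pixels, a 0.32 um lateral PSF, shot
#' noise from a photon-counting detector, a cortical extracellular-space
#' (ECS) volume fraction of 23%, capillaries of 3.7 um lumen FWHM flanked by
#' 0.58 um perivascular spaces, ~6 um phagocytic cups with content classes
#' in proportions 63.1/30.8/6.1% (lysed/intact/both), process speeds of
#' 0.07 um/s over 17.1 um (neuropil paths) and 0.12 um/s over 28.1 um
#' (cell-body paths) at one frame per 20 s, and a 47.5% dye-clearance drop
#' between 1 h and 4 h.
#'
#' @param seed integer seed fixing every random draw.
#' @param ny,nx field size in pixels.
#' @param dx micrometres per pixel (isotropic).
#' @param psf_fwhm_xy lateral PSF full width at half maximum, um.
#' @param psf_fwhm_z axial PSF FWHM, um (unused by the 2D generators).
#' @param noise list: `photon_peak` expected photon count at unit intensity
#'   (0 disables shot noise); `read_sigma` Gaussian read noise sd in
#'   intensity units.
#' @param vf_true ground-truth ECS volume fraction in (0, 1).
#' @param vessel list: `lumen_fwhm_um` mean lumen FWHM; `lumen_sd_um`
#'   between-vessel sd; `pvs_fwhm_um` mean perivascular-space FWHM;
#'   `coupling_slope` um of PVS width per um of lumen width;
#'   `coupling_noise_sigma` sd of the PVS-width residual (`NULL` derives it
#'   from `target_r`); `target_r` population Pearson correlation between
#'   lumen and PVS widths; `n_vessels`; `dx_um` pixel size of the vessel
#'   field (finer than the survey default so sub-micron PVS widths are
#'   well sampled).
#' @param lesion list: `n_cups`; `cup_diameter_um` mean/sd of interior
#'   diameter; `content_probs` probabilities of (lysed, intact, both);
#'   `exact_counts` use the rounded integer split instead of a multinomial
#'   draw; `n_frames`; `dt_s`; `cup_frames` frames each cup persists.
#' @param trajectories list: per-class tibs `n`, `speed_um_s`,
#'   `path_length_um`; plus `jitter_sigma_um`, `dt_s`, `arrival_radius_um`.
#' @param clearance list: `target_drop` fractional drop over `interval_h`
#'   (start, end); or `lambda_per_h` directly.
#' @param beads list: `n`, `fwhm_um` image-domain spot FWHM, `dx_um`
#'   bead-field pixel size, `amplitude`.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L,
                           ny = 512L, nx = 512L, dx = 0.16,
                           psf_fwhm_xy = 0.32, psf_fwhm_z = 0.925,
                           noise = list(),
                           vf_true = 0.23,
                           vessel = list(),
                           lesion = list(),
                           trajectories = list(),
                           clearance = list(),
                           beads = list()) {
  noise <- modifyList(list(photon_peak = 200, read_sigma = 0.005), noise)
  vessel <- modifyList(list(lumen_fwhm_um = 3.7, lumen_sd_um = 1.0,
                            pvs_fwhm_um = 0.58, coupling_slope = 0.12,
                            coupling_noise_sigma = NULL, target_r = 0.838,
                            n_vessels = 500L, dx_um = 0.08), vessel)
  lesion <- modifyList(list(n_cups = 130L,
                            cup_diameter_um = c(mean = 6, sd = 1),
                            content_probs = c(lysed = 0.631, intact = 0.308,
                                              both = 0.061),
                            exact_counts = FALSE,
                            n_frames = 24L, dt_s = 20, cup_frames = 2L), lesion)
  user_classes <- trajectories$classes
  trajectories <- modifyList(
    list(classes = list(
           neuropil = list(n = 29L, speed_um_s = 0.07, path_length_um = 17.1),
           cell_bodies = list(n = 14L, speed_um_s = 0.12, path_length_um = 28.1)),
         jitter_sigma_um = 0.1, dt_s = 20, arrival_radius_um = 2),
    trajectories)
  # a user-supplied class list replaces the defaults outright (modifyList
  # would merge the two sets of named classes)
  if (!is.null(user_classes)) trajectories$classes <- user_classes
  clearance <- modifyList(list(target_drop = 0.475, interval_h = c(1, 4),
                               lambda_per_h = NULL, t_max_h = 5,
                               dt_h = 0.5, i0 = 100), clearance)
  beads <- modifyList(list(n = 50L, fwhm_um = 0.212, dx_um = 0.04,
                           amplitude = 1), beads)
  if (abs(sum(lesion$content_probs) - 1) > 1e-8)
    stop("lesion content probabilities must sum to 1")
  if (!(vf_true > 0 && vf_true < 1)) stop("vf_true must lie in (0, 1)")
  if (is.null(vessel$coupling_noise_sigma)) {
    r <- vessel$target_r
    vessel$coupling_noise_sigma <-
      vessel$coupling_slope * vessel$lumen_sd_um * sqrt(1 / r^2 - 1)
  }
  structure(list(seed = as.integer(seed), ny = as.integer(ny),
                 nx = as.integer(nx), dx = dx,
                 psf_fwhm_xy = psf_fwhm_xy, psf_fwhm_z = psf_fwhm_z,
                 noise = noise, vf_true = vf_true, vessel = vessel,
                 lesion = lesion, trajectories = trajectories,
                 clearance = clearance, beads = beads),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("phantom_config: seed %d, %dx%d px @ %g um, PSF %g um, vf %g\n",
              x$seed, x$ny, x$nx, x$dx, x$psf_fwhm_xy, x$vf_true))
  invisible(x)
}
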