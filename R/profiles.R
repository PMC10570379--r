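#' Extract an intensity line profile by bilinear interpolation
#'
#' Samples the image along the segment p0 -> p1 at pixel-pitch spacing;
#' when `averaging_width > 1`, the value at each station is the mean over
#' that many parallel lines offset perpendicular to the segment at pixel
#' pitch (the standard way to reduce noise when measuring widths across
#' vessels).
#'
#' @param image numeric matrix (y, x) or an [image_stack()] (first plane
#'   used unless `t`/`c`/`z` given).
#' @param p0,p1 endpoints `c(y, x)` in micrometres.
#' @param geometry a [pixel_geometry()]; taken from the stack if omitted.
#' @param averaging_width odd number of parallel lines to average.
#' @param t,c,z plane selectors for stack input.
#' @return object of class `line_profile`: `positions` (um along the line,
#'   starting at 0), `values`, `endpoints`, `averaging_width`, `spacing`.
#' @export
extract_line_profile <- function(image, p0, p1, geometry = NULL,
                                 averaging_width = 1L, t = 1, c = 1, z = 1) {
  if (inherits(image, "image_stack")) {
    geometry <- geometry %||% image$geometry
    image <- get_frame(image, t, c, z)
  }
  if (is.null(geometry)) stop("geometry required for matrix input")
  if (averaging_width < 1 || averaging_width %% 2 == 0)
    stop("averaging_width must be odd and >= 1")
  dx <- geometry$dx
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop("profile endpoints coincide")
  n <- floor(len / dx) + 1L
  if (n < 2) stop("profile too short for the pixel pitch")
  tt <- seq(0, (n - 1) * dx, by = dx)
  u <- (p1 - p0) / len                    # unit tangent (y, x), um
  nv <- c(-u[2], u[1])                    # unit normal
  offs <- (seq_len(averaging_width) - (averaging_width + 1) / 2) * dx
  vals <- matrix(NA_real_, n, averaging_width)
  for (k in seq_along(offs)) {
    py <- (p0[1] + tt * u[1] + offs[k] * nv[1]) / dx
    px <- (p0[2] + tt * u[2] + offs[k] * nv[2]) / dx
    vals[, k] <- bilinear_sample(image, py, px)
  }
  if (anyNA(vals)) stop("line (or an averaged parallel line) exits the image")
  structure(list(positions = tt, values = rowMeans(vals),
                 endpoints = rbind(p0, p1),
                 averaging_width = averaging_width, spacing = dx),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("line_profile: %d samples over %.2f um (avg width %d)\n",
              length(x$positions), max(x$positions), x$averaging_width))
  invisible(x)
}

# Deterministic moment-based starting point for a single-Gaussian fit.
gaussian_moments_init <- function(pos, val) {
  baseline <- median(val)
  i <- which.max(abs(val - baseline))
  amplitude <- val[i] - baseline
  center <- pos[i]
  wts <- pmax(if (amplitude >= 0) val - baseline else baseline - val, 0)
  sigma <- if (sum(wts) > 0)
    sqrt(sum(wts * (pos - center)^2) / sum(wts)) else diff(range(pos)) / 6
  sigma <- max(sigma, mean(diff(pos)) / 2)
  list(baseline = baseline, amplitude = amplitude, center = center,
       sigma = sigma)
}

fit_gaussian_once <- function(pos, val) {
  init <- gaussian_moments_init(pos, val)
  df <- data.frame(x = pos, y = val)
  spc <- mean(diff(pos))
  # an exact moment start on noiseless data can leave the optimizer with a
  # degenerate gradient; deterministic perturbed restarts cover that case
  starts <- list(
    init,
    modifyList(init, list(sigma = init$sigma * 1.2,
                          center = init$center + spc / 3)),
    modifyList(init, list(sigma = init$sigma * 0.7,
                          center = init$center - spc / 3,
                          baseline = init$baseline + 0.05 * init$amplitude)))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
        start = list(b = st$baseline, a = st$amplitude,
                     mu = st$center, s = st$sigma),
        lower = c(-Inf, -Inf, min(pos), spc / 10),
        upper = c(Inf, Inf, max(pos), diff(range(pos))),
        control = nls.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (!is.null(fit)) {
    p <- coef(fit)
    return(list(baseline = unname(p["b"]), amplitude = unname(p["a"]),
                center = unname(p["mu"]), sigma = abs(unname(p["s"])),
                rmse = sqrt(mean(residuals(fit)^2))))
  }
  # last resort: derivative-free least squares (Levenberg-Marquardt's
  # model matrix can be singular on noise-free symmetric profiles)
  ssr <- function(par) {
    r <- val - (par[1] + par[2] * exp(-(pos - par[3])^2 / (2 * par[4]^2)))
    sum(r * r)
  }
  op <- tryCatch(
    stats::optim(c(init$baseline, init$amplitude, init$center, init$sigma),
                 ssr, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(op)) return(NULL)
  list(baseline = op$par[1], amplitude = op$par[2], center = op$par[3],
       sigma = abs(op$par[4]), rmse = sqrt(op$value / length(val)))
}

#' Fit a Gaussian peak or trough to a line profile and report its FWHM
#'
#' Least-squares fit of baseline + amplitude * exp(-(x - center)^2 /
#' (2 sigma^2)) with a deterministic moment-based start. FWHM =
#' 2 sqrt(2 ln 2) sigma. A trough is fitted as a peak on the negated
#' profile, giving a signed (negative) amplitude through one code path.
#'
#' @param profile a `line_profile`, or anything with numeric `positions`
#'   and `values`.
#' @param polarity `"auto"` picks the sign with lower RMSE.
#' @return object of class `gaussian_fit`: amplitude (signed), center,
#'   sigma, baseline, fwhm (all um / a.u.), rmse, converged.
#' @export
fit_gaussian_fwhm <- function(profile, polarity = c("auto", "peak", "trough")) {
  polarity <- match.arg(polarity)
  pos <- profile$positions; val <- profile$values
  if (length(pos) < 7) stop("need at least 7 samples to fit")
  if (diff(range(val)) == 0) stop("constant profile: nothing to fit")
  fits <- list()
  if (polarity %in% c("auto", "peak")) fits$peak <- fit_gaussian_once(pos, val)
  if (polarity %in% c("auto", "trough")) {
    f <- fit_gaussian_once(pos, -val)
    if (!is.null(f)) {
      f$baseline <- -f$baseline; f$amplitude <- -f$amplitude
      fits$trough <- f
    }
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    return(structure(list(amplitude = NA_real_, center = NA_real_,
                          sigma = NA_real_, baseline = NA_real_,
                          fwhm = NA_real_, rmse = NA_real_, converged = FALSE),
                     class = "gaussian_fit"))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "rmse"))]]
  converged <- best$center >= min(pos) && best$center <= max(pos)
  # in auto mode require the chosen polarity to match the fitted sign
  structure(list(amplitude = best$amplitude, center = best$center,
                 sigma = best$sigma, baseline = best$baseline,
                 fwhm = FWHM_PER_SIGMA * best$sigma, rmse = best$rmse,
                 converged = converged),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit: fwhm %.4f um (sigma %.4f), amp %.3g, rmse %.3g%s\n",
              x$fwhm, x$sigma, x$amplitude, x$rmse,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Measure lateral resolution from a field of isolated beads
#'
#' Detects local maxima above `detect_threshold` of the image maximum,
#' fits orthogonal x and y Gaussian profiles through each, and reports
#' per-bead FWHMs. Beads closer than 3x the median FWHM to a neighbour are
#' flagged `crowded` and excluded from the field mean (their mutual light
#' would bias the widths).
#'
#' @param stack single-plane [image_stack()].
#' @param detect_threshold fraction of the image maximum.
#' @param window_px half-window (pixels) of the fitted profiles.
#' @return data.frame (one row per bead: y_um, x_um, fwhm_x_um, fwhm_y_um,
#'   crowded) with attributes `mean_fwhm_um` (crowd-excluded field mean of
#'   both axes) and `n_used`.
#' @export
measure_bead_resolution <- function(stack, detect_threshold = 0.5,
                                    window_px = 10L) {
  img <- get_frame(stack)
  dx <- stack$geometry$dx
  ny <- nrow(img); nx <- ncol(img)
  empty_out <- function() {
    out <- data.frame(y_um = numeric(0), x_um = numeric(0),
                      fwhm_x_um = numeric(0), fwhm_y_um = numeric(0),
                      crowded = logical(0))
    attr(out, "mean_fwhm_um") <- NA_real_; attr(out, "n_used") <- 0L
    out
  }
  rng <- range(img)
  if (diff(rng) <= 1e-12) return(empty_out())   # flat field: nothing to detect
  # threshold on the intensity range so a non-zero background does not count
  thr <- rng[1] + detect_threshold * diff(rng)
  # local maxima over a 5x5 neighbourhood
  mx <- img
  for (dy in -2:2) for (dxs in -2:2) {
    if (dy == 0 && dxs == 0) next
    sh <- matrix(-Inf, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy); xs <- max(1, 1 + dxs):min(nx, nx + dxs)
    sh[ys - dy, xs - dxs] <- img[ys, xs]
    mx <- pmax(mx, sh)
  }
  peaks <- which(img >= thr & img >= mx, arr.ind = TRUE)
  if (nrow(peaks) == 0) return(empty_out())
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    py <- peaks[i, 1]; px <- peaks[i, 2]
    if (py <= window_px || py > ny - window_px ||
        px <= window_px || px > nx - window_px) return(NULL)
    fx <- tryCatch(fit_gaussian_fwhm(list(
      positions = (-window_px:window_px) * dx,
      values = img[py, (px - window_px):(px + window_px)]), "peak"),
      error = function(e) NULL)
    fy <- tryCatch(fit_gaussian_fwhm(list(
      positions = (-window_px:window_px) * dx,
      values = img[(py - window_px):(py + window_px), px]), "peak"),
      error = function(e) NULL)
    if (is.null(fx) || is.null(fy) || !fx$converged || !fy$converged)
      return(NULL)
    data.frame(y_um = (py - 1) * dx, x_um = (px - 1) * dx,
               fwhm_x_um = fx$fwhm, fwhm_y_um = fy$fwhm)
  })
  out <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(out) || nrow(out) == 0) return(empty_out())
  med_fwhm <- median(c(out$fwhm_x_um, out$fwhm_y_um))
  dmat <- as.matrix(stats::dist(out[, c("y_um", "x_um")]))
  diag(dmat) <- Inf
  out$crowded <- apply(dmat, 1, min) < 3 * med_fwhm
  used <- !out$crowded
  attr(out, "mean_fwhm_um") <-
    mean(c(out$fwhm_x_um[used], out$fwhm_y_um[used]))
  attr(out, "n_used") <- sum(used)
  out
}

#' Signal-to-noise time course along a fixed line
#'
#' SNR of frame t is defined as (max - min) of the line profile divided by
#' the standard deviation of the background ROI pixels of that frame
#' (peak-to-trough contrast over noise). Also reports the linear trend of
#' SNR across frames and its t statistic, to test for bleaching.
#'
#' @param stack time-series [image_stack()].
#' @param p0,p1 line endpoints in um.
#' @param background_roi [roi_mask()] of a structure-free region.
#' @param averaging_width passed to [extract_line_profile()].
#' @return data.frame (frame, t_s, snr) with attributes `slope_per_s` and
#'   `slope_t` (t statistic of the trend).
#' @export
snr_timecourse <- function(stack, p0, p1, background_roi,
                           averaging_width = 1L) {
  nt <- dim(stack)[1]
  if (nt < 2) stop("need at least 2 frames")
  dt <- stack$geometry$dt %||% 1
  snr <- vapply(seq_len(nt), function(t) {
    prof <- extract_line_profile(stack, p0, p1, t = t,
                                 averaging_width = averaging_width)
    bg <- get_frame(stack, t)[background_roi$mask]
    s <- sd(bg)
    if (s == 0) stop("zero background standard deviation")
    (max(prof$values) - min(prof$values)) / s
  }, 0)
  out <- data.frame(frame = seq_len(nt), t_s = (seq_len(nt) - 1) * dt,
                    snr = snr)
  fit <- lm(snr ~ t_s, data = out)
  attr(out, "slope_per_s") <- unname(coef(fit)[2])
  attr(out, "slope_t") <- unname(summary(fit)$coefficients[2, "t value"])
  out
}

#' Fractional fluorescence change relative to baseline
#'
#' F0 is the mean of the first `baseline_frames` samples; the result is
#' (F - F0) / F0.
#'
#' @param trace numeric intensity time series.
#' @param baseline_frames number of initial frames defining F0.
#' @export
delta_f_over_f <- function(trace, baseline_frames) {
  if (baseline_frames < 1 || baseline_frames >= length(trace))
    stop("baseline_frames must be >= 1 and < length(trace)")
  f0 <- mean(trace[seq_len(baseline_frames)])
  if (f0 <= 0) stop("non-positive baseline F0")
  (trace - f0) / f0
}

#' Percentage intensity drop between two time points
#'
#' Intensities at t1 and t2 are obtained by linear interpolation of the
#' series; the drop is 100 (I(t1) - I(t2)) / I(t1). Invariant to rescaling
#' the whole series by a positive constant.
#'
#' @param series data.frame with columns `time_h` and `intensity`.
#' @param t1,t2 times in hours, `t1 < t2`, inside the sampled range.
#' @return drop in percent.
#' @export
intensity_drop <- function(series, t1, t2) {
  stopifnot(t1 < t2)
  rng <- range(series$time_h)
  if (t1 < rng[1] || t2 > rng[2]) stop("t1/t2 outside the sampled range")
  i1 <- approx(series$time_h, series$intensity, t1)$y
  i2 <- approx(series$time_h, series$intensity, t2)$y
  if (i1 <= 0) stop("non-positive intensity at t1")
  100 * (i1 - i2) / i1
}
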