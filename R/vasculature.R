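#' Vessel centreline polyline
#'
#' @param points_um matrix with columns (y, x) in micrometres, >= 2 rows.
#' @param label vessel label.
#' @export
vessel_axis <- function(points_um, label = "vessel") {
  points_um <- as.matrix(points_um)
  if (nrow(points_um) < 2) stop("vessel axis needs at least 2 points")
  seg <- sqrt(rowSums(diff(points_um)^2))
  if (any(seg <= 0)) stop("vessel axis has zero-length segments")
  structure(list(points = points_um, label = label, seg_lengths = seg),
            class = "vessel_axis")
}

# Point and unit tangent at arc-length s along a polyline.
axis_point_tangent <- function(axis, s) {
  cum <- c(0, cumsum(axis$seg_lengths))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
  i <- min(i, nrow(axis$points) - 1L)
  p0 <- axis$points[i, ]; p1 <- axis$points[i + 1L, ]
  u <- (p1 - p0) / axis$seg_lengths[i]
  list(point = p0 + (s - cum[i]) * u, tangent = u)
}

#' Place line profiles orthogonal to a vessel axis
#'
#' Stations are placed every `spacing` um along the centreline; at each, a
#' profile perpendicular to the local tangent is extracted, centred on the
#' axis with total length 2 * `half_length`. Stations whose profile would
#' leave the image are skipped with a warning.
#'
#' @param image matrix or [image_stack()].
#' @param axis a [vessel_axis()].
#' @param spacing_um station spacing, um.
#' @param half_length_um profile half-length, um; must exceed the expected
#'   lumen radius plus PVS width.
#' @param averaging_width odd number of averaged parallel lines.
#' @param geometry [pixel_geometry()] for matrix input.
#' @param t,c,z plane selectors for stack input.
#' @return list of `line_profile`s; each carries attributes `station_um`
#'   and `vessel_label`.
#' @export
place_orthogonal_profiles <- function(image, axis, spacing_um, half_length_um,
                                      averaging_width = 5L, geometry = NULL,
                                      t = 1, c = 1, z = 1) {
  stopifnot(spacing_um > 0, half_length_um > 0)
  total <- sum(axis$seg_lengths)
  stations <- seq(0, total, by = spacing_um)
  out <- list()
  for (s in stations) {
    pt <- axis_point_tangent(axis, s)
    nv <- c(-pt$tangent[2], pt$tangent[1])
    p0 <- pt$point - half_length_um * nv
    p1 <- pt$point + half_length_um * nv
    prof <- tryCatch(
      extract_line_profile(image, p0, p1, geometry = geometry,
                           averaging_width = averaging_width,
                           t = t, c = c, z = z),
      error = function(e) NULL)
    if (is.null(prof)) {
      warning(sprintf("station %.1f um skipped: profile exits image", s))
      next
    }
    attr(prof, "station_um") <- s
    attr(prof, "vessel_label") <- axis$label
    out[[length(out) + 1L]] <- prof
  }
  out
}

#' Measure lumen and perivascular-space widths from one cross-section
#'
#' Fits the composite model
#' baseline + A_L G(x; mu_L, s_L) + A_R G(x; mu_R, s_R) - A_0 G(x; mu_0, s_0)
#' (two perivascular peaks flanking one lumen trough, all amplitudes
#' non-negative, mu_L < mu_0 < mu_R) simultaneously, because flanks and
#' trough overlap at capillary scale. FWHMs are 2.3548 sigma of the fitted
#' components. A flank whose fitted amplitude falls below `amp_sig` times
#' the residual sd, or below 2% of the profile range, is reported missing;
#' a profile with no significant trough is flagged `no_vessel`. When the
#' full two-flank model cannot be fitted, reduced models (one flank, trough
#' only) compete on residual RMSE.
#'
#' @param profile a `line_profile` across the vessel.
#' @param amp_sig amplitude-significance multiple of the residual sd.
#' @return data.frame of class `vessel_measurement`: vessel_label,
#'   station_um, lumen_fwhm_um, pvs_fwhm_left_um, pvs_fwhm_right_um, rmse,
#'   quality ("ok", "no_vessel").
#' @export
measure_vessel_cross_section <- function(profile, amp_sig = 3) {
  pos <- profile$positions; val <- profile$values
  lab <- attr(profile, "vessel_label") %||% "vessel"
  stat <- attr(profile, "station_um") %||% NA_real_
  no_vessel <- function() {
    data.frame(vessel_label = lab, station_um = stat,
               lumen_fwhm_um = NA_real_, pvs_fwhm_left_um = NA_real_,
               pvs_fwhm_right_um = NA_real_, rmse = NA_real_,
               quality = "no_vessel")
  }
  if (diff(range(val)) < 1e-12) return(no_vessel())
  base0 <- median(val)
  i0 <- which.min(val)
  depth <- base0 - val[i0]
  if (depth <= 0.05 * diff(range(val))) return(no_vessel())
  mu0 <- pos[i0]
  # trough width at half depth for the sigma start
  half <- base0 - depth / 2
  below <- which(val < half)
  s0 <- if (length(below) > 1) diff(range(pos[below])) / FWHM_PER_SIGMA
        else 4 * profile$spacing
  # flank peak starts: maxima on each side of the trough
  left <- which(pos < mu0 - s0); right <- which(pos > mu0 + s0)
  if (length(left) < 3 || length(right) < 3) return(no_vessel())
  iL <- left[which.max(val[left])]; iR <- right[which.max(val[right])]
  spc <- profile$spacing
  rng <- range(pos)
  df <- data.frame(x = pos, y = val)
  amp_floor <- 0.05 * diff(range(val))
  # candidate models: both flanks, one flank, trough only. The full model is
  # singular when an absent flank's amplitude converges to the bound, so the
  # reduced models are genuine fallbacks, selected by RMSE.
  fit_model <- function(sides, s0_scale = 1) {
    terms <- "b - a0 * exp(-(x - mu0)^2 / (2 * s0^2))"
    start <- list(b = base0, a0 = depth, mu0 = mu0, s0 = max(s0, spc) * s0_scale)
    lower <- c(b = -Inf, a0 = 0, mu0 = rng[1], s0 = spc / 2)
    upper <- c(b = Inf, a0 = Inf, mu0 = rng[2], s0 = diff(rng))
    if ("L" %in% sides) {
      terms <- paste(terms, "+ aL * exp(-(x - muL)^2 / (2 * sL^2))")
      start <- c(start, list(aL = max(val[iL] - base0, amp_floor),
                             muL = pos[iL], sL = 2 * spc * s0_scale))
      lower <- c(lower, aL = 0, muL = rng[1], sL = spc / 4)
      upper <- c(upper, aL = Inf, muL = rng[2], sL = diff(rng))
    }
    if ("R" %in% sides) {
      terms <- paste(terms, "+ aR * exp(-(x - muR)^2 / (2 * sR^2))")
      start <- c(start, list(aR = max(val[iR] - base0, amp_floor),
                             muR = pos[iR], sR = 2 * spc * s0_scale))
      lower <- c(lower, aR = 0, muR = rng[1], sR = spc / 4)
      upper <- c(upper, aR = Inf, muR = rng[2], sR = diff(rng))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(stats::as.formula(paste("y ~", terms)), data = df,
                        start = start, lower = lower, upper = upper,
                        control = nls.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit))
      return(list(par = coef(fit), rmse = sqrt(mean(residuals(fit)^2))))
    # derivative-free fallback: Levenberg-Marquardt can be singular on
    # noise-free profiles; Nelder-Mead on the same least-squares objective
    nm_start <- unlist(start)
    model_val <- function(par) {
      v0 <- par["b"] - abs(par["a0"]) *
        exp(-(pos - par["mu0"])^2 / (2 * par["s0"]^2))
      if ("L" %in% sides)
        v0 <- v0 + abs(par["aL"]) *
          exp(-(pos - par["muL"])^2 / (2 * par["sL"]^2))
      if ("R" %in% sides)
        v0 <- v0 + abs(par["aR"]) *
          exp(-(pos - par["muR"])^2 / (2 * par["sR"]^2))
      v0
    }
    op <- tryCatch(
      stats::optim(nm_start, function(par) sum((val - model_val(par))^2),
                   method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(op)) return(NULL)
    par <- op$par
    for (nm in grep("^(a|s)", names(par), value = TRUE)) par[nm] <- abs(par[nm])
    list(par = par, rmse = sqrt(op$value / length(val)))
  }
  fit <- NULL; sides <- character(0)
  best_rmse <- Inf
  excellent <- 1e-3 * diff(range(val))
  for (cand in list(c("L", "R"), "L", "R", character(0))) {
    f <- fit_model(cand)
    if (is.null(f)) f <- fit_model(cand, s0_scale = 1.2)
    if (is.null(f)) next
    if (f$rmse < best_rmse) { fit <- f; sides <- cand; best_rmse <- f$rmse }
    if (best_rmse < excellent) break   # full model fits essentially perfectly
  }
  if (is.null(fit)) return(no_vessel())
  p <- fit$par
  resid_sd <- fit$rmse
  if (p["a0"] < amp_sig * resid_sd) return(no_vessel())
  # a flank must rise above the fit noise AND above 2% of the profile range
  # (3 x resid_sd alone accepts arbitrarily small peaks on noiseless data)
  amp_min <- max(amp_sig * resid_sd, 0.02 * diff(range(val)))
  side_fwhm <- function(side) {
    if (!side %in% sides) return(NA_real_)
    a <- p[paste0("a", side)]; mu <- p[paste0("mu", side)]
    sg <- abs(p[paste0("s", side)])
    ordered <- if (side == "L") mu < p["mu0"] else mu > p["mu0"]
    if (!ordered || a < amp_min) return(NA_real_)
    unname(FWHM_PER_SIGMA * sg)
  }
  data.frame(vessel_label = lab, station_um = stat,
             lumen_fwhm_um = FWHM_PER_SIGMA * abs(unname(p["s0"])),
             pvs_fwhm_left_um = side_fwhm("L"),
             pvs_fwhm_right_um = side_fwhm("R"),
             rmse = fit$rmse, quality = "ok")
}

#' Correlation between perivascular-space width and vessel diameter
#'
#' Aggregates measurements per vessel and computes the Pearson correlation
#' between lumen FWHM and PVS width. Pairing rule: by default each vessel
#' contributes its lumen FWHM paired with the mean of its available PVS
#' side measurements; `pairing = "sides"` instead treats every measured
#' side as its own pair.
#'
#' @param measurements data.frame of [measure_vessel_cross_section()] rows.
#' @param pairing `"mean"` or `"sides"`.
#' @return list of class `correlation_result`: `r`, `p`, `n`.
#' @export
pvs_vessel_correlation <- function(measurements, pairing = c("mean", "sides")) {
  pairing <- match.arg(pairing)
  m <- measurements[measurements$quality == "ok", , drop = FALSE]
  agg <- lapply(split(m, m$vessel_label), function(g) {
    lum <- mean(g$lumen_fwhm_um, na.rm = TRUE)
    sides <- c(g$pvs_fwhm_left_um, g$pvs_fwhm_right_um)
    sides <- sides[!is.na(sides)]
    if (length(sides) == 0) return(NULL)
    if (pairing == "mean")
      data.frame(lumen = lum, pvs = mean(sides))
    else
      data.frame(lumen = lum, pvs = sides)
  })
  d <- do.call(rbind, Filter(Negate(is.null), agg))
  if (is.null(d) || nrow(d) < 3) stop("need at least 3 vessels with a PVS measurement")
  if (sd(d$lumen) == 0 || sd(d$pvs) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n = nrow(d)),
                     class = "correlation_result"))
  ct <- cor.test(d$lumen, d$pvs, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Measure every vessel of a stack at mid-axis cross-sections
#'
#' Convenience wrapper: for each supplied axis, extracts `n_stations`
#' profiles around the middle of the centreline and measures each with
#' [measure_vessel_cross_section()].
#'
#' @param stack [image_stack()].
#' @param axes list of [vessel_axis()].
#' @param frames frame index per axis (recycled).
#' @param half_length_um profile half-length.
#' @param n_stations stations per vessel, centred on the axis midpoint.
#' @param spacing_um distance between stations.
#' @param averaging_width odd number of averaged parallel lines.
#' @return data.frame of measurements (one row per station).
#' @export
measure_vessels <- function(stack, axes, frames = 1L, half_length_um = 6,
                            n_stations = 1L, spacing_um = 2,
                            averaging_width = 5L) {
  frames <- rep_len(frames, length(axes))
  rows <- list()
  for (i in seq_along(axes)) {
    ax <- axes[[i]]
    total <- sum(ax$seg_lengths)
    mids <- total / 2 +
      (seq_len(n_stations) - (n_stations + 1) / 2) * spacing_um
    for (s in mids) {
      pt <- axis_point_tangent(ax, s)
      nv <- c(-pt$tangent[2], pt$tangent[1])
      prof <- tryCatch(
        extract_line_profile(stack, pt$point - half_length_um * nv,
                             pt$point + half_length_um * nv,
                             averaging_width = averaging_width,
                             t = frames[i]),
        error = function(e) NULL)
      if (is.null(prof)) next
      attr(prof, "station_um") <- s
      attr(prof, "vessel_label") <- ax$label
      rows[[length(rows) + 1L]] <- measure_vessel_cross_section(prof)
    }
  }
  do.call(rbind, rows)
}
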