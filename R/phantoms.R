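#' Apply Gaussian PSF blur and detector noise to a stack
#'
#' Image formation model for all phantoms: each (t, c, z) plane is convolved
#' with a unit-sum separable Gaussian kernel of the given FWHM
#' (sigma = FWHM / 2.3548) using a circular boundary, which conserves the
#' image mean exactly; then Poisson shot noise is drawn at `photon_peak`
#' scaling (counts ~ Pois(photon_peak * I) / photon_peak) and Gaussian read
#' noise of sd `read_sigma` is added. Negative results are clipped at 0.
#'
#' @param stack an [image_stack()].
#' @param psf_fwhm_xy lateral PSF FWHM in um; 0 = no blur.
#' @param noise list with `photon_peak` (0 = no shot noise) and `read_sigma`.
#' @param seed integer seed; the draw is fully reproducible.
#' @return blurred/noisy [image_stack()].
#' @export
apply_psf_noise <- function(stack, psf_fwhm_xy,
                            noise = list(photon_peak = 0, read_sigma = 0),
                            seed = 1L) {
  stopifnot(psf_fwhm_xy >= 0)
  pk <- noise$photon_peak %||% 0
  rs <- noise$read_sigma %||% 0
  sigma_px <- psf_fwhm_xy / FWHM_PER_SIGMA / stack$geometry$dx
  kern <- gaussian_kernel_1d(sigma_px)
  d <- dim(stack$data)
  out <- stack$data
  if (length(kern) > 1)
    for (t in seq_len(d[1])) for (cc in seq_len(d[2])) for (z in seq_len(d[3]))
      out[t, cc, z, , ] <- conv_sep_circular_cpp(out[t, cc, z, , ], kern)
  withr::with_seed(seed, {
    if (pk > 0) out[] <- rpois(length(out), pk * out) / pk
    if (rs > 0) out <- out + rnorm(length(out), 0, rs)
  })
  if (pk > 0 || rs > 0) out <- pmax(out, 0)
  image_stack(out, stack$geometry, normalized = FALSE)
}

#' Neuropil phantom for volume-fraction estimation
#'
#' Builds a binary tissue geometry (ECS bright = 1, cells dark = 0) by
#' packing randomly sized elliptical cell/neurite cross-sections until the
#' ECS pixel fraction of the neuropil region matches `vf_true` within
#' `tol` (0.002), keeps one rectangular pure-ECS plateau (side at least
#' 3x the PSF FWHM) free of cells, then applies PSF blur and noise.
#'
#' @param config a [phantom_config()].
#' @param tol tolerance on the achieved ECS fraction.
#' @return list with `stack` (blurred/noisy [image_stack()]) and `truth`:
#'   `ecs_mask` ([roi_mask()] of the pre-blur ECS), `vf_achieved`,
#'   `plateau` (0-based pixel rect `c(y0, x0, y1, x1)`), `n_cells`.
#' @export
make_neuropil_phantom <- function(config, tol = 0.002) {
  ny <- config$ny; nx <- config$nx; dx <- config$dx
  vf <- config$vf_true
  side <- max(20L, ceiling(3 * config$psf_fwhm_xy / dx))
  withr::with_seed(config$seed, {
    y0 <- sample.int(ny - side, 1L) - 1L
    x0 <- sample.int(nx - side, 1L) - 1L
    plateau <- c(y0, x0, y0 + side - 1L, x0 + side - 1L)
    # keep a blur margin of cells around the plateau so it stays pure after PSF
    marg <- ceiling(2 * config$psf_fwhm_xy / dx)
    ecs <- matrix(TRUE, ny, nx)
    protected <- matrix(FALSE, ny, nx)
    protected[(max(1, y0 + 1 - marg)):(min(ny, y0 + side + marg)),
              (max(1, x0 + 1 - marg)):(min(nx, x0 + side + marg))] <- TRUE
    n_neuropil <- sum(!protected)
    ecs_count <- n_neuropil              # TRUE pixels outside the plateau zone
    n_cells <- 0L; tries <- 0L; shrink <- 1
    # run to the target itself (not the tolerance band's upper edge, which
    # would leave a one-sided +tol bias in the achieved fraction)
    while (ecs_count / n_neuropil > vf && tries < 200000L) {
      tries <- tries + 1L
      # neurite-scale cross-sections 0.4-2 um across, log-uniform: VF regions
      # are neuropil (fine processes, no somata), and this grain keeps the
      # ROI-to-ROI dispersion of 10-um regions near field observations
      diam <- exp(runif(1, log(0.4), log(2))) * shrink
      ry <- diam / 2 / dx * runif(1, 0.6, 1.4)
      rx <- diam / 2 / dx * runif(1, 0.6, 1.4)
      # centres drawn from a domain extended by the ellipse radius so that
      # coverage is stationary up to the field border (confining centres to
      # the field would leave a brighter rim and over-pack the interior)
      cy <- runif(1, -ry, ny - 1 + ry); cx <- runif(1, -rx, nx - 1 + rx)
      idx <- ellipse_indices(ny, nx, cy, cx, ry, rx)
      if (length(idx) == 0) next
      idx <- idx[!protected[idx]]
      removed <- sum(ecs[idx])
      if ((ecs_count - removed) / n_neuropil < vf - tol) {
        shrink <- shrink * 0.8           # would overshoot: try smaller
        if (shrink < 0.02) break
        next
      }
      ecs[idx] <- FALSE
      ecs_count <- ecs_count - removed
      n_cells <- n_cells + 1L
    }
    achieved <- ecs_count / n_neuropil
    if (abs(achieved - vf) > tol)
      stop(sprintf("could not reach target ECS fraction %.3f (achieved %.3f)",
                   vf, achieved))
    img <- matrix(0, ny, nx); img[ecs] <- 1
    stack <- image_stack(img, pixel_geometry(dx))
    stack <- apply_psf_noise(stack, config$psf_fwhm_xy, config$noise,
                             seed = config$seed + 1L)
  })
  list(stack = stack,
       truth = list(ecs_mask = roi_mask(ecs, "ecs"),
                    vf_achieved = achieved, plateau = plateau,
                    n_cells = n_cells))
}

# Composite vessel cross-section: baseline + two PVS peaks - lumen trough.
# d: signed perpendicular distance from the vessel axis (um).
vessel_profile_value <- function(d, lumen_fwhm, pvs_fwhm, baseline = 0.5,
                                 peak_amp = 0.35) {
  s0 <- lumen_fwhm / FWHM_PER_SIGMA
  sp <- pvs_fwhm / FWHM_PER_SIGMA
  mu <- lumen_fwhm / 2 + pvs_fwhm
  v <- baseline +
    peak_amp * (exp(-(d - mu)^2 / (2 * sp^2)) + exp(-(d + mu)^2 / (2 * sp^2))) -
    baseline * exp(-d^2 / (2 * s0^2))
  pmax(v, 0)
}

#' Vessel phantom: dark lumens flanked by bright perivascular stripes
#'
#' Each vessel is a straight tube whose intensity cross-section is built
#' directly as baseline + two Gaussian peaks (the perivascular space, PVS)
#' minus one Gaussian trough (the lumen) with specified image-domain FWHMs,
#' so the printed widths are directly recoverable by profile fitting. Lumen
#' FWHM D is drawn Normal(lumen_fwhm_um, lumen_sd_um); the PVS width of both
#' sides of a vessel is the single annulus width
#' w = pvs_fwhm_um + coupling_slope * (D - mean D) + eps,
#' eps ~ Normal(0, coupling_noise_sigma), giving population correlation
#' r = b sd_D / sqrt(b^2 sd_D^2 + sd_eps^2). Vessels are laid out in
#' parallel groups of `per_frame` per time frame to respect a packing limit.
#'
#' @param config a [phantom_config()].
#' @param per_frame vessels per frame.
#' @param frame_px frame side in pixels.
#' @return list with `stack` and `truth`; `truth$vessels` is a data.frame
#'   with one row per vessel (frame, angle, offsets, endpoints of the axis
#'   in um, true `lumen_fwhm_um` and `pvs_fwhm_um`), `truth$axes` a list of
#'   [vessel_axis()] polylines.
#' @export
make_vessel_phantom <- function(config, per_frame = 1L, frame_px = 176L) {
  v <- config$vessel; dx <- v$dx_um %||% config$dx
  n <- v$n_vessels
  stopifnot(n >= 1)
  n_frames <- ceiling(n / per_frame)
  ext_um <- (frame_px - 1) * dx
  withr::with_seed(config$seed, {
    D <- rnorm(n, v$lumen_fwhm_um, v$lumen_sd_um)
    D <- pmin(pmax(D, 1.2), v$lumen_fwhm_um + 4 * v$lumen_sd_um)
    w <- v$pvs_fwhm_um + v$coupling_slope * (D - v$lumen_fwhm_um) +
      rnorm(n, 0, v$coupling_noise_sigma)
    w <- pmax(w, 0.2)
    arr <- array(0, dim = c(n_frames, 1, 1, frame_px, frame_px))
    rows <- vector("list", n)
    axes <- vector("list", n)
    yy <- matrix(rep(0:(frame_px - 1) * dx, frame_px), frame_px)        # y um
    xx <- t(yy)                                                         # x um
    cy <- ext_um / 2; cx <- ext_um / 2
    for (f in seq_len(n_frames)) {
      ids <- ((f - 1) * per_frame + 1):min(f * per_frame, n)
      theta <- runif(1, 0, pi)                    # axis direction this frame
      nvec <- c(-sin(theta), cos(theta))          # unit normal (y, x)
      k <- length(ids)
      # evenly spaced perpendicular offsets with a random dither
      span <- ext_um * 0.72
      offs <- if (k == 1) runif(1, -0.3, 0.3)
              else (seq_len(k) - (k + 1) / 2) / k * span + runif(k, -0.3, 0.3)
      dist0 <- (yy - cy) * nvec[1] + (xx - cx) * nvec[2]   # signed perp dist
      img <- matrix(0.5, frame_px, frame_px)
      for (i in seq_len(k)) {
        id <- ids[i]
        dperp <- dist0 - offs[i]
        img <- img + (vessel_profile_value(dperp, D[id], w[id]) - 0.5)
        tvec <- c(cos(theta), sin(theta))          # tangent (y, x)
        p0 <- c(cy, cx) + offs[i] * nvec - 0.45 * ext_um * tvec
        p1 <- c(cy, cx) + offs[i] * nvec + 0.45 * ext_um * tvec
        rows[[id]] <- data.frame(vessel = id, frame = f, angle = theta,
                                 offset_um = offs[i],
                                 y0 = p0[1], x0 = p0[2], y1 = p1[1], x1 = p1[2],
                                 lumen_fwhm_um = D[id], pvs_fwhm_um = w[id])
        axes[[id]] <- vessel_axis(rbind(p0, p1), label = paste0("v", id))
      }
      arr[f, 1, 1, , ] <- pmax(img, 0)
    }
    stack <- image_stack(arr, pixel_geometry(dx, dt = 1))
    if ((config$noise$photon_peak %||% 0) > 0 || (config$noise$read_sigma %||% 0) > 0)
      stack <- apply_psf_noise(stack, 0, config$noise, seed = config$seed + 1L)
  })
  list(stack = stack,
       truth = list(vessels = do.call(rbind, rows), axes = axes))
}

#' Two-channel lesion time series with phagocytic cups
#'
#' Channel 1 (EGFP, microglia): dark background with bright, near-radial
#' process strokes converging on the lesion and, for each cup, a bright
#' annulus with a dark interior of the sampled diameter. Channel 2
#' (shadow): bright extracellular background with a central lesion disc
#' containing dark intact (dye-negative) blebs and bright lysed
#' (dye-positive) patches; each cup interior is painted according to its
#' drawn content class (lysed = dye-bright, intact = dye-dark, both =
#' lysed in the first half of its lifetime and intact in the second, so
#' both states occur at different frames). The field emulates confocal
#' lesion movies: 80 nm pixels and a 0.212 um PSF by default, so the
#' median-filter/PSF rim around a cup stays small relative to its
#' interior.
#'
#' @param config a [phantom_config()].
#' @return list with `stack` (t, 2 channels) and `truth`: `cups` data.frame
#'   (cup, class, frame_start, frame_end, y_um, x_um, diameter_um),
#'   `lesion_mask`, plus per-frame true `intact`/`lysed` logical arrays
#'   (y, x, t).
#' @export
make_lesion_series <- function(config) {
  L <- config$lesion
  ny <- L$ny %||% 768L; nx <- L$nx %||% 768L
  dx <- L$dx_um %||% 0.08
  psf <- L$psf_fwhm_um %||% 0.212
  nf <- L$n_frames
  stopifnot(nf >= 8)
  bg_egfp <- 0.05; fg_egfp <- 1.0
  bg_sh <- 0.75; lysed_v <- 1.0; intact_v <- 0.02
  ring_um <- L$ring_um %||% 0.8
  withr::with_seed(config$seed, {
    n <- L$n_cups
    classes <- draw_cup_classes(n, L$content_probs, L$exact_counts)
    egfp <- array(bg_egfp, dim = c(ny, nx, nf))
    shadow <- array(bg_sh, dim = c(ny, nx, nf))
    true_intact <- array(FALSE, dim = c(ny, nx, nf))
    true_lysed <- array(FALSE, dim = c(ny, nx, nf))
    # lesion disc: centred, radius 40% of the field
    cyl <- (ny - 1) / 2; cxl <- (nx - 1) / 2
    rl <- 0.4 * min(ny, nx)
    lesion_idx <- ellipse_indices(ny, nx, cyl, cxl, rl, rl)
    lesion_mask <- matrix(FALSE, ny, nx); lesion_mask[lesion_idx] <- TRUE
    # background lesion material: dark blebs + lysed patches in every frame
    for (f in seq_len(nf)) {
      sh <- shadow[, , f]
      for (b in seq_len(25)) {
        r_um <- runif(1, 0.8, 2.0)
        ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * (rl - r_um / dx)
        cy <- cyl + rad * sin(ang); cx <- cxl + rad * cos(ang)
        idx <- ellipse_indices(ny, nx, cy, cx, r_um / dx, r_um / dx)
        if (b <= 13) { sh[idx] <- intact_v; true_intact[, , f][idx] <- TRUE }
        else { sh[idx] <- lysed_v; true_lysed[, , f][idx] <- TRUE }
      }
      shadow[, , f] <- sh
    }
    # place the cups without overlap, away from borders
    cups <- data.frame(cup = integer(0), class = character(0),
                       frame_start = integer(0), frame_end = integer(0),
                       y_um = numeric(0), x_um = numeric(0),
                       diameter_um = numeric(0))
    keepout <- matrix(FALSE, ny, nx)     # cup discs, all frames: no strokes
    if (n > 0) {
      diam <- rnorm(n, L$cup_diameter_um["mean"], L$cup_diameter_um["sd"])
      diam <- pmin(pmax(diam, 4), 10)
      f0 <- sample.int(nf - L$cup_frames + 1L, n, replace = TRUE)
      occupied <- array(FALSE, dim = c(ny, nx, nf))
      yc <- xc <- numeric(n)
      for (i in seq_len(n)) {
        r_out <- (diam[i] / 2 + ring_um) / dx
        placed <- FALSE
        # check an extended +/- 1 frame window so holes of different cups
        # can never touch across time (26-connected labelling would merge);
        # resample the start frame when a position cannot be found
        for (attempt in seq_len(25)) {
          for (try in seq_len(200)) {
            cy <- runif(1, r_out + 2, ny - r_out - 3)
            cx <- runif(1, r_out + 2, nx - r_out - 3)
            idx <- ellipse_indices(ny, nx, cy, cx, r_out + 3, r_out + 3)
            fr_chk <- max(1L, f0[i] - 1L):min(nf, f0[i] + L$cup_frames)
            lin <- rep(idx, length(fr_chk)) +
              rep((fr_chk - 1L) * ny * nx, each = length(idx))
            if (!any(occupied[lin])) { placed <- TRUE; break }
          }
          if (placed) break
          f0[i] <- sample.int(nf - L$cup_frames + 1L, 1L)
        }
        if (!placed) stop("could not place cup without overlap; field too crowded")
        yc[i] <- cy; xc[i] <- cx
        keepout[ellipse_indices(ny, nx, cy, cx, r_out + 4, r_out + 4)] <- TRUE
        fr <- f0[i]:(f0[i] + L$cup_frames - 1L)
        ring <- setdiff(ellipse_indices(ny, nx, cy, cx, r_out, r_out),
                        ellipse_indices(ny, nx, cy, cx, diam[i] / 2 / dx,
                                        diam[i] / 2 / dx))
        interior <- ellipse_indices(ny, nx, cy, cx, diam[i] / 2 / dx,
                                    diam[i] / 2 / dx)
        for (j in seq_along(fr)) {
          f <- fr[j]
          eg <- egfp[, , f]
          eg[ring] <- fg_egfp
          egfp[, , f] <- eg
          sh <- shadow[, , f]
          ti <- true_intact[, , f]; tl <- true_lysed[, , f]
          content <- switch(classes[i],
            lysed = "lysed", intact = "intact",
            both = if (j <= ceiling(length(fr) / 2)) "lysed" else "intact")
          if (content == "lysed") { sh[interior] <- lysed_v; tl[interior] <- TRUE
                                    ti[interior] <- FALSE }
          else { sh[interior] <- intact_v; ti[interior] <- TRUE
                 tl[interior] <- FALSE }
          sh[ring] <- intact_v        # the microglial ring itself excludes dye
          shadow[, , f] <- sh; true_intact[, , f] <- ti; true_lysed[, , f] <- tl
          occupied[ellipse_indices(ny, nx, cy, cx, r_out + 3, r_out + 3) +
                   (f - 1L) * ny * nx] <- TRUE
        }
      }
      cups <- data.frame(cup = seq_len(n), class = classes,
                         frame_start = f0, frame_end = f0 + L$cup_frames - 1L,
                         y_um = yc * dx, x_um = xc * dx, diameter_um = diam)
    }
    # static microglial processes: near-radial bright strokes toward the
    # lesion centre, skirting cup discs so every detected hole is a cup
    proc <- matrix(FALSE, ny, nx)
    wr <- max(2, round(0.25 / dx))
    for (p in seq_len(12)) {
      ang0 <- runif(1, 0, 2 * pi)
      y <- cyl + 0.52 * ny * sin(ang0); x <- cxl + 0.52 * nx * cos(ang0)
      len <- runif(1, 0.3, 0.8) * 0.5 * min(ny, nx)
      ang <- atan2(cyl - y, cxl - x)
      nsteps <- ceiling(len / 2)
      for (st in seq_len(nsteps)) {
        ang <- ang + rnorm(1, 0, 0.06)
        y <- y + 2 * sin(ang); x <- x + 2 * cos(ang)
        if (y < 1 || y > ny - 2 || x < 1 || x > nx - 2) break
        idx <- ellipse_indices(ny, nx, y, x, wr, wr)
        idx <- idx[!keepout[idx]]
        proc[idx] <- TRUE
      }
    }
    for (f in seq_len(nf)) {
      eg <- egfp[, , f]
      eg[proc & eg <= bg_egfp] <- fg_egfp
      egfp[, , f] <- eg
      sh <- shadow[, , f]
      sh[proc & sh == bg_sh] <- intact_v    # processes exclude dye too
      shadow[, , f] <- sh
    }
    arr <- array(0, dim = c(nf, 2, 1, ny, nx))
    arr[, 1, 1, , ] <- aperm(egfp, c(3, 1, 2))
    arr[, 2, 1, , ] <- aperm(shadow, c(3, 1, 2))
    stack <- image_stack(arr, pixel_geometry(dx, dt = L$dt_s))
    # confocal lesion movies are bright: the <2% dye-positive band is only
    # 2% of the grey range, so the shot-noise sd after median filtering must
    # sit well below it
    stack <- apply_psf_noise(
      stack, psf,
      modifyList(config$noise,
                 list(photon_peak = L$photon_peak %||% 2000)),
      seed = config$seed + 1L)
  })
  list(stack = stack,
       truth = list(cups = cups, lesion_mask = roi_mask(lesion_mask, "lesion"),
                    intact = true_intact, lysed = true_lysed))
}

draw_cup_classes <- function(n, probs, exact_counts) {
  labs <- names(probs) %||% c("lysed", "intact", "both")
  if (n == 0) return(character(0))
  if (exact_counts) {
    k <- floor(n * probs)
    rem <- n - sum(k)
    if (rem > 0) {
      extra <- order(n * probs - k, decreasing = TRUE)[seq_len(rem)]
      k[extra] <- k[extra] + 1
    }
    sample(rep(labs, times = k))
  } else {
    sample(labs, n, replace = TRUE, prob = probs)
  }
}

#' Synthetic microglial process-tip trajectories
#'
#' Each tip starts at distance (path_length + arrival_radius) from its
#' lesion point and advances toward it at the class's nominal speed, one
#' step per frame, with isotropic Gaussian positional jitter; the final
#' approach step is truncated so the tip lands exactly at the arrival
#' radius, making the ground-truth cumulative distance at arrival equal the
#' configured path length in the noiseless limit. A few post-arrival frames
#' are appended so every trajectory has at least 8 frames.
#'
#' @param config a [phantom_config()].
#' @return list with `table` (data.frame: tip_id, class, frame, t_s, y_um,
#'   x_um) and `truth` (per-tip class, nominal speed, path length,
#'   lesion point).
#' @export
make_trajectories <- function(config) {
  tr <- config$trajectories
  withr::with_seed(config$seed, {
    rows <- list(); truth <- list(); tid <- 0L
    for (cls in names(tr$classes)) {
      p <- tr$classes[[cls]]
      step <- p$speed_um_s * tr$dt_s
      for (i in seq_len(p$n)) {
        tid <- tid + 1L
        lesion <- c(y = runif(1, 40, 60), x = runif(1, 40, 60))
        ang <- runif(1, 0, 2 * pi)
        dir <- c(sin(ang), cos(ang))
        start <- lesion + (p$path_length_um + tr$arrival_radius_um) * dir
        m <- floor(p$path_length_um / step)
        last <- p$path_length_um - m * step
        steps <- c(rep(step, m), if (last > 1e-9) last)
        pos <- start
        path <- list(pos)
        for (s in steps) { pos <- pos - s * dir; path[[length(path) + 1L]] <- pos }
        while (length(path) < 8) path[[length(path) + 1L]] <- pos
        pm <- do.call(rbind, path)
        if (tr$jitter_sigma_um > 0)
          pm <- pm + matrix(rnorm(length(pm), 0, tr$jitter_sigma_um), nrow(pm))
        nfr <- nrow(pm)
        rows[[tid]] <- data.frame(tip_id = tid, class = cls,
                                  frame = seq_len(nfr),
                                  t_s = (seq_len(nfr) - 1) * tr$dt_s,
                                  y_um = pm[, 1], x_um = pm[, 2])
        truth[[tid]] <- data.frame(tip_id = tid, class = cls,
                                   speed_um_s = p$speed_um_s,
                                   path_length_um = p$path_length_um,
                                   lesion_y_um = lesion[1], lesion_x_um = lesion[2])
      }
    }
  })
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Exponential dye-clearance intensity time course
#'
#' I(t) = I0 exp(-lambda t). When a target fractional drop d over
#' \[t1, t2\] is configured, lambda = ln(1 / (1 - d)) / (t2 - t1), so the
#' drop between t1 and t2 equals d exactly.
#'
#' @param config a [phantom_config()].
#' @return data.frame with columns `time_h`, `intensity`.
#' @export
make_clearance_series <- function(config) {
  cl <- config$clearance
  lam <- cl$lambda_per_h %||%
    (log(1 / (1 - cl$target_drop)) / diff(cl$interval_h))
  t <- seq(0, cl$t_max_h, by = cl$dt_h)
  data.frame(time_h = t, intensity = cl$i0 * exp(-lam * t))
}

#' Field of isolated fluorescent beads
#'
#' Sub-resolution beads are rendered directly as 2D Gaussian spots of the
#' configured image-domain FWHM at random positions separated by at least
#' 4x the FWHM, over a dark background, then shot/read noise is applied.
#'
#' @param config a [phantom_config()].
#' @param field_px field side in pixels.
#' @return list with `stack` and `truth` (data.frame of positions in um and
#'   the true FWHM).
#' @export
make_bead_field <- function(config, field_px = 256L) {
  b <- config$beads
  dx <- b$dx_um
  sig_px <- b$fwhm_um / FWHM_PER_SIGMA / dx
  min_sep <- 4 * b$fwhm_um / dx
  withr::with_seed(config$seed, {
    pos <- matrix(numeric(0), ncol = 2)
    guard <- 0L
    while (nrow(pos) < b$n && guard < 20000L) {
      guard <- guard + 1L
      cand <- c(runif(1, 10, field_px - 11), runif(1, 10, field_px - 11))
      if (nrow(pos) == 0 ||
          min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >= min_sep)
        pos <- rbind(pos, cand)
    }
    if (nrow(pos) < b$n) stop("could not place all beads with required separation")
    img <- matrix(0.01, field_px, field_px)
    ys <- 0:(field_px - 1)
    for (i in seq_len(nrow(pos))) {
      gy <- exp(-(ys - pos[i, 1])^2 / (2 * sig_px^2))
      gx <- exp(-(ys - pos[i, 2])^2 / (2 * sig_px^2))
      img <- img + b$amplitude * outer(gy, gx)
    }
    stack <- image_stack(img, pixel_geometry(dx))
    if ((config$noise$photon_peak %||% 0) > 0)
      stack <- apply_psf_noise(stack, 0, config$noise, seed = config$seed + 1L)
  })
  truth <- if (nrow(pos) > 0)
    data.frame(y_um = pos[, 1] * dx, x_um = pos[, 2] * dx,
               fwhm_um = b$fwhm_um)
  else data.frame(y_um = numeric(0), x_um = numeric(0), fwhm_um = numeric(0))
  list(stack = stack, truth = truth)
}
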