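#' Estimate the pure-extracellular-space reference intensity
#'
#' The volume-fraction estimator needs the fluorescence level of a region
#' of pure extracellular fluid, obtained either from a designated ROI
#' (e.g. a perivascular space large enough to contain the excitation spot)
#' or, when none is available, as the mean of the brightest fraction of
#' pixels in the field, which approximate pure ECS.
#'
#' @param image numeric matrix or [image_stack()] (first plane).
#' @param reference a [roi_mask()] (ROI mode) or a [top_fraction()]
#'   (default brightest 0.1% of the field).
#' @return reference intensity (a.u.).
#' @details ROI mode refuses regions containing saturated pixels: the
#'   normalization is only meaningful while the detector is in its linear
#'   range.
#' @export
estimate_pure_ecs_intensity <- function(image, reference = top_fraction()) {
  sat <- NULL
  if (inherits(image, "image_stack")) {
    if (!is.null(image$saturated)) sat <- image$saturated[1, 1, 1, , ]
    image <- get_frame(image)
  }
  if (inherits(reference, "roi_mask")) {
    if (!any(reference$mask)) stop("empty reference ROI")
    if (!is.null(sat) && any(sat[reference$mask]))
      stop("reference ROI contains saturated pixels")
    mean(image[reference$mask])
  } else if (inherits(reference, "top_fraction")) {
    v <- sort(as.vector(image), decreasing = TRUE)
    k <- max(1L, round(unclass(reference) * length(v)))
    mean(v[seq_len(k)])
  } else stop("reference must be a roi_mask or a top_fraction()")
}

#' Top-fraction specifier for the pure-ECS reference
#'
#' Marks a fraction of the brightest pixels to use as the pure-ECS
#' reference when no perivascular ROI is designated.
#'
#' @param fraction fraction of pixels in (0, 1]; default 0.001 (0.1%).
#' @export
top_fraction <- function(fraction = 0.001) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction <= 1)
  structure(fraction, class = "top_fraction")
}

#' Estimate the extracellular-space volume fraction per ROI
#'
#' The ECS volume fraction (VF) of a neuropil region is the mean
#' fluorescence intensity of the region normalized by the pure-ECS
#' reference: vf = (mean(ROI) - background) / (I_ECS - background). Because
#' convolution with a unit-sum PSF conserves local means, the estimate is a
#' priori independent of the microscope's spatial resolution. Background
#' defaults to 0 (no offset subtraction); pass a dark-ROI mean or fixed
#' offset when the detector has one. Estimates pushed outside \[0, 1\] by
#' noise are clipped and flagged.
#'
#' @param image numeric matrix or [image_stack()].
#' @param neuropil_rois list of [roi_mask()] (or a single mask).
#' @param ecs_reference a [roi_mask()], a [top_fraction()], or a
#'   precomputed numeric reference intensity.
#' @param background numeric offset or [roi_mask()] whose mean is used.
#' @return data.frame of class `vf_estimates`: roi_label, mean_intensity,
#'   ecs_reference, background, vf, clipped; attributes `mean_pct`,
#'   `sem_pct`, `n`.
#' @export
estimate_vf <- function(image, neuropil_rois,
                        ecs_reference = top_fraction(), background = 0) {
  img <- if (inherits(image, "image_stack")) get_frame(image) else image
  if (inherits(neuropil_rois, "roi_mask")) neuropil_rois <- list(neuropil_rois)
  iecs <- if (is.numeric(ecs_reference) && !inherits(ecs_reference, "top_fraction"))
    ecs_reference else estimate_pure_ecs_intensity(image, ecs_reference)
  bg <- if (inherits(background, "roi_mask")) mean(img[background$mask])
        else background
  if (bg >= iecs) stop("background must be below the pure-ECS reference")
  rows <- lapply(neuropil_rois, function(r) {
    if (!any(r$mask)) stop("empty neuropil ROI: ", r$label)
    m <- mean(img[r$mask])
    vf <- (m - bg) / (iecs - bg)
    data.frame(roi_label = r$label, mean_intensity = m, ecs_reference = iecs,
               background = bg, vf = min(max(vf, 0), 1),
               clipped = vf < 0 || vf > 1)
  })
  out <- do.call(rbind, rows)
  s <- summarize_vf(out)
  attr(out, "mean_pct") <- s$mean_pct
  attr(out, "sem_pct") <- s$sem_pct
  attr(out, "n") <- s$n
  class(out) <- c("vf_estimates", "data.frame")
  out
}

#' Summarize volume-fraction estimates as mean +/- SEM in percent
#'
#' @param estimates a `vf_estimates` data.frame (or anything with a `vf`
#'   column), or a numeric vector of fractions.
#' @return list `mean_pct`, `sem_pct` (0 with `sem_defined = FALSE` when
#'   n = 1), `n`.
#' @export
summarize_vf <- function(estimates) {
  vf <- if (is.numeric(estimates)) estimates else estimates$vf
  n <- length(vf)
  stopifnot(n >= 1)
  sem <- if (n > 1) sd(vf) / sqrt(n) * 100 else 0
  list(mean_pct = mean(vf) * 100, sem_pct = sem, n = n,
       sem_defined = n > 1)
}

#' Random square neuropil ROIs avoiding a region
#'
#' Test/phantom helper: places `n` square ROIs of the given side uniformly
#' at random, avoiding the pure-ECS plateau (and a border margin). ROIs are
#' drawn independently and may overlap (each is an unbiased sample of the
#' neuropil either way); set `allow_overlap = FALSE` to forbid it.
#'
#' @param ny,nx field size in pixels.
#' @param n number of ROIs.
#' @param side_px ROI side in pixels.
#' @param avoid optional 0-based rect `c(y0, x0, y1, x1)` to stay clear of.
#' @param margin_px margin kept around `avoid` and the borders.
#' @param allow_overlap permit overlapping ROIs.
#' @param seed integer seed.
#' @return list of [roi_mask()].
#' @export
random_neuropil_rois <- function(ny, nx, n, side_px, avoid = NULL,
                                 margin_px = 4L, allow_overlap = TRUE,
                                 seed = 1L) {
  withr::with_seed(seed, {
    rois <- list(); guard <- 0L
    taken <- matrix(FALSE, ny, nx)
    while (length(rois) < n && guard < 20000L) {
      guard <- guard + 1L
      y0 <- sample.int(ny - side_px - 2L * margin_px, 1L) + margin_px
      x0 <- sample.int(nx - side_px - 2L * margin_px, 1L) + margin_px
      ys <- y0:(y0 + side_px - 1L); xs <- x0:(x0 + side_px - 1L)
      if (!is.null(avoid) &&
          y0 + side_px - 1L >= avoid[1] + 1L - margin_px &&
          y0 <= avoid[3] + 1L + margin_px &&
          x0 + side_px - 1L >= avoid[2] + 1L - margin_px &&
          x0 <= avoid[4] + 1L + margin_px) next
      if (!allow_overlap && any(taken[ys, xs])) next
      taken[ys, xs] <- TRUE
      m <- matrix(FALSE, ny, nx); m[ys, xs] <- TRUE
      rois[[length(rois) + 1L]] <-
        roi_mask(m, label = sprintf("roi%02d", length(rois) + 1L))
    }
    if (length(rois) < n) stop("could not place all ROIs")
    rois
  })
}
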