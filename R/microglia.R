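#' Parameters of the phagocytic-triage pipeline
#'
#' @param median_radius disk radius (pixels) of the spatial median filter.
#' @param intact_threshold fraction of the normalized range; pixels of the
#'   inverted shadow image strictly above it are intact (dye-negative)
#'   cellular material.
#' @param lysed_threshold fraction; inverted pixels strictly below it are
#'   lysed (dye-positive) material.
#' @param cup_diameter_range admissible equivalent diameters of a
#'   phagocytic cup, um (centred on the typical ~6 um cup).
#' @param min_circularity minimum mean circularity 4 pi A / P^2 of a cup.
#' @param norm_pct robust normalization percentiles `c(lo, hi)`.
#' @export
triage_params <- function(median_radius = 4L, intact_threshold = 0.70,
                          lysed_threshold = 0.02,
                          cup_diameter_range = c(3, 12),
                          min_circularity = 0.6,
                          norm_pct = c(0.1, 99.9)) {
  stopifnot(lysed_threshold >= 0, lysed_threshold < intact_threshold,
            intact_threshold <= 1,
            cup_diameter_range[1] > 0,
            cup_diameter_range[1] < cup_diameter_range[2])
  structure(list(median_radius = as.integer(median_radius),
                 intact_threshold = intact_threshold,
                 lysed_threshold = lysed_threshold,
                 cup_diameter_range = cup_diameter_range,
                 min_circularity = min_circularity,
                 norm_pct = norm_pct),
            class = "triage_params")
}

#' Preprocess a shadow (COSHI) time series for triage
#'
#' Per frame: disk median filter of the configured radius, robust
#' percentile normalization to \[0, 1\], then inversion, so that cellular
#' (dark) structures become bright and the fractional grey-level thresholds
#' apply.
#'
#' @param stack single-channel [image_stack()] time series.
#' @param params a [triage_params()].
#' @return normalized, inverted [image_stack()].
#' @export
preprocess_coshi <- function(stack, params = triage_params()) {
  d <- dim(stack)
  if (d[2] != 1) stop("preprocess_coshi expects a single shadow channel")
  out <- stack$data
  for (t in seq_len(d[1])) for (z in seq_len(d[3])) {
    fr <- stack$data[t, 1, z, , ]
    if (params$median_radius > 0)
      fr <- median_filter_disk_cpp(fr, params$median_radius)
    out[t, 1, z, , ] <- fr
  }
  st <- image_stack(out, stack$geometry)
  st <- normalize_frames(st, params$norm_pct[1], params$norm_pct[2])
  invert_stack(st)
}

#' Threshold an inverted shadow stack into intact and lysed masks
#'
#' On the inverted, normalized image, intact (dye-negative) structures are
#' pixels strictly above `intact_threshold` and lysed (dye-positive)
#' material strictly below `lysed_threshold`; the masks are disjoint by
#' construction.
#'
#' @param inverted_stack normalized, inverted [image_stack()].
#' @param params a [triage_params()].
#' @return list of two logical arrays (y, x, t): `intact`, `lysed`.
#' @export
threshold_tissue_state <- function(inverted_stack, params = triage_params()) {
  if (!isTRUE(inverted_stack$normalized)) stop("stack must be normalized")
  d <- dim(inverted_stack)
  nt <- d[1]; ny <- d[4]; nx <- d[5]
  intact <- array(FALSE, dim = c(ny, nx, nt))
  lysed <- array(FALSE, dim = c(ny, nx, nt))
  for (t in seq_len(nt)) {
    fr <- inverted_stack$data[t, 1, 1, , ]
    intact[, , t] <- fr > params$intact_threshold
    lysed[, , t] <- fr < params$lysed_threshold
  }
  list(intact = intact, lysed = lysed)
}

#' Automatic per-frame lesion ROI
#'
#' The developing lesion is, per frame, the morphological closing of the
#' union of lysed pixels and intact pixels absent from the baseline
#' frames' intact union (newly dark, i.e. blebbing/dysmorphic material).
#' An expert-drawn ROI should override this rule when available.
#'
#' @param masks list with `intact` and `lysed` (y, x, t) arrays, as from
#'   [threshold_tissue_state()].
#' @param baseline_frames number of initial frames defining the baseline.
#' @param close_radius_px closing disk radius, pixels.
#' @return logical array (y, x, t).
#' @export
detect_lesion_roi <- function(masks, baseline_frames = 1L,
                              close_radius_px = 5L) {
  stopifnot(baseline_frames >= 1)
  d <- dim(masks$intact)
  nt <- d[3]
  base_union <- apply(masks$intact[, , seq_len(baseline_frames), drop = FALSE],
                      c(1, 2), any)
  brush <- EBImage::makeBrush(2L * close_radius_px + 1L, shape = "disc")
  out <- array(FALSE, dim = d)
  for (t in seq_len(nt)) {
    raw <- masks$lysed[, , t] | (masks$intact[, , t] & !base_union)
    cl <- EBImage::closing(EBImage::Image(raw * 1), brush)
    out[, , t] <- as.matrix(cl) > 0.5
  }
  out
}

#' Detect phagocytic cups by fill-holes subtraction
#'
#' Per frame the EGFP microglia channel is binarized (per-frame Otsu by
#' default, or a fixed threshold), holes are filled, and the original
#' binary image is subtracted, leaving exactly the enclosed background
#' regions -- the interiors of ring/cup-shaped structures. The hole pixels
#' are then grouped over (x, y, t) with 26-connectivity, and components are
#' kept whose per-frame equivalent diameter lies in the configured range
#' and whose mean circularity (4 pi A / P^2) reaches the minimum; retained
#' cups are ranked by circularity.
#'
#' @param egfp_stack single-channel [image_stack()] time series.
#' @param params a [triage_params()].
#' @param binarize `"otsu"` or a fixed threshold in (0, 1) applied to the
#'   per-frame normalized image.
#' @return list: `cups` data.frame (cup_id, frame, y_um, x_um, area_um2,
#'   eq_diam_um, circularity), `labels` integer array (y, x, t) of retained
#'   cup ids, `holes` logical array of all hole pixels.
#' @export
detect_phagocytic_cups <- function(egfp_stack, params = triage_params(),
                                   binarize = "otsu") {
  d <- dim(egfp_stack)
  if (d[2] != 1) stop("expects a single EGFP channel")
  nt <- d[1]; ny <- d[4]; nx <- d[5]
  dx <- egfp_stack$geometry$dx
  norm <- normalize_frames(egfp_stack, params$norm_pct[1], params$norm_pct[2])
  holes <- array(FALSE, dim = c(ny, nx, nt))
  for (t in seq_len(nt)) {
    fr <- norm$data[t, 1, 1, , ]
    thr <- if (identical(binarize, "otsu"))
      EBImage::otsu(EBImage::Image(fr)) else binarize
    bin <- fr > thr
    filled <- as.matrix(EBImage::fillHull(EBImage::Image(bin * 1))) > 0.5
    holes[, , t] <- filled & !bin
  }
  lab <- label3d26_cpp(holes, dim(holes))
  n_lab <- attr(lab, "n_labels")
  empty <- data.frame(cup_id = integer(0), frame = integer(0),
                      y_um = numeric(0), x_um = numeric(0),
                      area_um2 = numeric(0), eq_diam_um = numeric(0),
                      circularity = numeric(0))
  if (n_lab == 0)
    return(list(cups = empty, labels = lab, holes = holes))
  # per-frame geometry of every component
  rows <- list()
  for (t in seq_len(nt)) {
    sl <- matrix(lab[, , t], ny, nx)
    if (!any(sl > 0)) next
    ft <- EBImage::computeFeatures.shape(sl)
    mom <- EBImage::computeFeatures.moment(sl)
    ids <- as.integer(rownames(ft) %||% seq_len(nrow(ft)))
    present <- ft[, "s.area"] > 0
    if (!any(present)) next
    # EBImage treats the first array dimension as x; our matrices are (y, x),
    # so m.cx is the row (y) centroid and m.cy the column (x) centroid
    rows[[length(rows) + 1L]] <- data.frame(
      cup_id = ids[present], frame = t,
      y_um = (mom[present, "m.cx"] - 1) * dx,
      x_um = (mom[present, "m.cy"] - 1) * dx,
      area_um2 = ft[present, "s.area"] * dx^2,
      eq_diam_um = 2 * sqrt(ft[present, "s.area"] * dx^2 / pi),
      circularity = pmin(4 * pi * ft[present, "s.area"] /
                           pmax(ft[present, "s.perimeter"], 1)^2, 1.05))
  }
  geo <- do.call(rbind, rows)
  if (is.null(geo) || nrow(geo) == 0)
    return(list(cups = empty, labels = lab, holes = holes))
  keep <- vapply(split(geo, geo$cup_id), function(g) {
    all(g$eq_diam_um >= params$cup_diameter_range[1] &
        g$eq_diam_um <= params$cup_diameter_range[2]) &&
      mean(g$circularity) >= params$min_circularity
  }, TRUE)
  kept_ids <- as.integer(names(keep))[keep]
  geo <- geo[geo$cup_id %in% kept_ids, , drop = FALSE]
  lab[!(lab %in% kept_ids)] <- 0L
  # rank by mean circularity (most circular first)
  if (nrow(geo) > 0) {
    rank_tbl <- sort(tapply(geo$circularity, geo$cup_id, mean),
                     decreasing = TRUE)
    geo$circ_rank <- match(as.character(geo$cup_id), names(rank_tbl))
    geo <- geo[order(geo$circ_rank, geo$frame), , drop = FALSE]
  }
  list(cups = geo, labels = lab, holes = holes)
}

#' Classify the contents of detected phagocytic cups
#'
#' A cup is positive for lysed (dye-positive) material in a frame if the
#' median of the binary lysed mask over its interior pixels is non-zero,
#' i.e. more than half its interior is lysed; likewise for intact. Over its
#' lifetime a cup is classed `lysed`, `intact`, `both` (positive for both,
#' in the same or different frames) or `empty`.
#'
#' @param detection result of [detect_phagocytic_cups()].
#' @param masks list with `intact` and `lysed` arrays, as from
#'   [threshold_tissue_state()].
#' @return list: `cups` (per cup: cup_id, class, n_frames), `per_frame`
#'   (cup_id, frame, pos_lysed, pos_intact), `summary` (counts and
#'   percentages per class).
#' @export
classify_cup_contents <- function(detection, masks) {
  geo <- detection$cups
  lab <- detection$labels
  if (nrow(geo) == 0)
    return(list(cups = data.frame(cup_id = integer(0), class = character(0),
                                  n_frames = integer(0)),
                per_frame = NULL,
                summary = triage_percentages(character(0))))
  d <- dim(masks$intact)
  pf <- lapply(seq_len(nrow(geo)), function(i) {
    t <- geo$frame[i]; id <- geo$cup_id[i]
    pix <- which(matrix(lab[, , t], d[1], d[2]) == id)
    if (length(pix) == 0)
      return(data.frame(cup_id = id, frame = t, pos_lysed = NA, pos_intact = NA))
    data.frame(cup_id = id, frame = t,
               pos_lysed = median(masks$lysed[, , t][pix]) > 0,
               pos_intact = median(masks$intact[, , t][pix]) > 0)
  })
  pf <- do.call(rbind, pf)
  cups <- do.call(rbind, lapply(split(pf, pf$cup_id), function(g) {
    anyL <- any(g$pos_lysed, na.rm = TRUE)
    anyI <- any(g$pos_intact, na.rm = TRUE)
    cls <- if (anyL && anyI) "both" else if (anyL) "lysed"
           else if (anyI) "intact" else "empty"
    data.frame(cup_id = g$cup_id[1], class = cls, n_frames = nrow(g))
  }))
  rownames(cups) <- NULL
  list(cups = cups, per_frame = pf,
       summary = triage_percentages(cups$class))
}

triage_percentages <- function(classes) {
  n <- length(classes)
  lv <- c("lysed", "intact", "both", "empty")
  cnt <- setNames(vapply(lv, function(l) sum(classes == l), 0L), lv)
  pct <- if (n > 0) 100 * cnt / n else setNames(rep(NA_real_, 4), lv)
  list(n_cups = n, counts = cnt, percent = pct)
}

#' Lesion-ROI vs phagocytic-cup enrichment statistics
#'
#' "In ROI" is the percentage of the developing lesion area occupied by
#' lysed (or intact) pixels, averaged over frames; "In PC" is the
#' percentage of phagocytic cups positive for lysed (or intact) contents,
#' averaged over frames with at least one cup. In PC exceeding In ROI
#' indicates that microglia preferentially engulf that tissue state.
#'
#' @param masks list with `intact`/`lysed` arrays.
#' @param lesion_roi logical array (y, x, t) or a single (y, x) mask
#'   recycled over frames.
#' @param classification result of [classify_cup_contents()].
#' @return list: `in_roi` (percent lysed, intact), `in_pc` (percent lysed,
#'   intact), `n_frames_with_cups`.
#' @export
enrichment_stats <- function(masks, lesion_roi, classification) {
  d <- dim(masks$intact); nt <- d[3]
  if (length(dim(lesion_roi)) == 2)
    lesion_roi <- array(lesion_roi, dim = c(dim(lesion_roi), nt))
  roi_l <- roi_i <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    roi <- lesion_roi[, , t]
    a <- sum(roi)
    if (a == 0) next
    roi_l[t] <- 100 * sum(masks$lysed[, , t] & roi) / a
    roi_i[t] <- 100 * sum(masks$intact[, , t] & roi) / a
  }
  pf <- classification$per_frame
  if (is.null(pf) || nrow(pf) == 0) {
    in_pc <- c(lysed = NA_real_, intact = NA_real_)
    nf <- 0L
  } else {
    by_f <- split(pf, pf$frame)
    pcl <- vapply(by_f, function(g) 100 * mean(g$pos_lysed, na.rm = TRUE), 0)
    pci <- vapply(by_f, function(g) 100 * mean(g$pos_intact, na.rm = TRUE), 0)
    in_pc <- c(lysed = mean(pcl), intact = mean(pci))
    nf <- length(by_f)
  }
  list(in_roi = c(lysed = mean(roi_l, na.rm = TRUE),
                  intact = mean(roi_i, na.rm = TRUE)),
       in_pc = in_pc, n_frames_with_cups = nf)
}

#' Motility metrics of a microglial process-tip trajectory
#'
#' Cumulative distance is the sum of frame-to-frame displacements from the
#' first frame to the arrival frame (the first frame within
#' `arrival_radius_um` of the lesion point, else the last frame). Mean
#' velocity averages the frame-to-frame speeds between the listed frames of
#' `velocity_frames` (1-based, default 3-7, the linear portion of the
#' trajectory), i.e. the displacements 3-4, 4-5, 5-6, 6-7 at the default.
#'
#' @param traj data.frame with columns `frame`, `y_um`, `x_um` (one tip).
#' @param lesion_point `c(y, x)` in um.
#' @param dt_s seconds per frame.
#' @param arrival_radius_um arrival distance threshold.
#' @param velocity_frames 1-based frame window for the velocity.
#' @return list of class `motility_metrics`: `cumulative_distance_um`,
#'   `mean_velocity_um_s`, `arrival_frame` (NA if never within radius),
#'   `arrived`.
#' @export
track_metrics <- function(traj, lesion_point, dt_s,
                          arrival_radius_um = 2, velocity_frames = 3:7) {
  traj <- traj[order(traj$frame), , drop = FALSE]
  n <- nrow(traj)
  if (n < 8) stop("need at least 8 frames for motility metrics")
  p <- as.matrix(traj[, c("y_um", "x_um")])
  step <- sqrt(rowSums(diff(p)^2))                  # length n - 1
  dist_to_lesion <- sqrt((p[, 1] - lesion_point[1])^2 +
                         (p[, 2] - lesion_point[2])^2)
  arr <- unname(which(dist_to_lesion <= arrival_radius_um))[1]
  arrived <- !is.na(arr)
  stop_at <- if (arrived) arr else n
  cum <- if (stop_at > 1) sum(step[seq_len(stop_at - 1)]) else 0
  vf <- velocity_frames
  idx <- vf[vf >= 1 & vf < n]
  idx <- idx[-length(idx)]                          # transitions within window
  if (length(idx) == 0) stop("velocity window outside trajectory")
  vel <- mean(step[idx]) / dt_s
  structure(list(cumulative_distance_um = cum, mean_velocity_um_s = vel,
                 arrival_frame = if (arrived) arr else NA_integer_,
                 arrived = arrived),
            class = "motility_metrics")
}

#' Classify a trajectory's path as through neuropil or around cell bodies
#'
#' Cell bodies are the large dark structures of the baseline shadow frame:
#' connected components of inverted intensity above the intact threshold
#' with equivalent diameter of at least `min_body_um`. The path class is
#' `cell_bodies` when the straight segment from the tip's baseline position
#' to the lesion point intersects that mask, else `neuropil`.
#'
#' @param traj data.frame with `y_um`, `x_um` (first row = baseline).
#' @param lesion_point `c(y, x)` um.
#' @param inverted_frame normalized inverted baseline shadow frame (matrix)
#'   or [image_stack()].
#' @param geometry [pixel_geometry()] for matrix input.
#' @param params a [triage_params()].
#' @param min_body_um minimum cell-body equivalent diameter.
#' @return `"cell_bodies"` or `"neuropil"`.
#' @export
classify_path <- function(traj, lesion_point, inverted_frame, geometry = NULL,
                          params = triage_params(), min_body_um = 5) {
  if (inherits(inverted_frame, "image_stack")) {
    geometry <- geometry %||% inverted_frame$geometry
    inverted_frame <- get_frame(inverted_frame)
  }
  dx <- geometry$dx
  dark <- inverted_frame > params$intact_threshold
  lab <- EBImage::bwlabel(EBImage::Image(dark * 1))
  labm <- as.matrix(lab)
  if (max(labm) > 0) {
    ft <- EBImage::computeFeatures.shape(labm)
    eq <- 2 * sqrt(ft[, "s.area"] * dx^2 / pi)
    big <- as.integer(rownames(ft))[eq >= min_body_um]
    body <- matrix(labm %in% big, nrow(labm), ncol(labm))
  } else body <- matrix(FALSE, nrow(labm), ncol(labm))
  if (!any(body)) return("neuropil")
  p0 <- c(traj$y_um[1], traj$x_um[1])
  seg_len <- sqrt(sum((lesion_point - p0)^2))
  n <- max(2L, ceiling(seg_len / (dx / 2)))
  tt <- seq(0, 1, length.out = n)
  ys <- (p0[1] + tt * (lesion_point[1] - p0[1])) / dx
  xs <- (p0[2] + tt * (lesion_point[2] - p0[2])) / dx
  v <- bilinear_sample(body * 1, ys, xs)
  if (any(v > 0.5, na.rm = TRUE)) "cell_bodies" else "neuropil"
}

#' Motility metrics for a cohort of tip trajectories
#'
#' Applies [track_metrics()] to every tip of a trajectory table (as
#' produced by [make_trajectories()]) using each tip's own lesion point.
#'
#' @param table data.frame with tip_id, frame, y_um, x_um (and optionally
#'   class).
#' @param truth data.frame with tip_id, lesion_y_um, lesion_x_um.
#' @param dt_s seconds per frame.
#' @param ... passed to [track_metrics()].
#' @return data.frame: tip_id, class, cumulative_distance_um,
#'   mean_velocity_um_s, arrival_frame, arrived.
#' @export
cohort_motility <- function(table, truth, dt_s, ...) {
  rows <- lapply(split(table, table$tip_id), function(tr) {
    tru <- truth[truth$tip_id == tr$tip_id[1], ]
    m <- track_metrics(tr, c(tru$lesion_y_um, tru$lesion_x_um), dt_s, ...)
    data.frame(tip_id = tr$tip_id[1],
               class = if ("class" %in% names(tr)) tr$class[1] else NA,
               cumulative_distance_um = m$cumulative_distance_um,
               mean_velocity_um_s = m$mean_velocity_um_s,
               arrival_frame = m$arrival_frame, arrived = m$arrived)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$tip_id), , drop = FALSE]
}
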