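#' Physical pixel geometry of an image stack
#'
#' @param dx,dy micrometres per pixel along x and y; `dy` defaults to `dx`.
#' @param dz micrometres per z plane, or `NULL` for 2D data.
#' @param dt seconds per frame, or `NULL` for single time points.
#' @return an object of class `pixel_geometry`.
#' @export
pixel_geometry <- function(dx, dy = dx, dz = NULL, dt = NULL) {
  vals <- c(dx = dx, dy = dy, dz = dz %||% NA_real_, dt = dt %||% NA_real_)
  chk <- vals[!is.na(vals)]
  if (any(chk <= 0)) stop("pixel geometry values must be strictly positive")
  structure(list(dx = dx, dy = dy, dz = dz, dt = dt),
            class = "pixel_geometry")
}

#' @export
print.pixel_geometry <- function(x, ...) {
  cat(sprintf("pixel_geometry: dx=%g um, dy=%g um", x$dx, x$dy))
  if (!is.null(x$dz)) cat(sprintf(", dz=%g um", x$dz))
  if (!is.null(x$dt)) cat(sprintf(", dt=%g s", x$dt))
  cat("\n")
  invisible(x)
}

#' Construct an image stack with fixed (t, c, z, y, x) axes
#'
#' The universal raster carrier for all pipelines. Data of lower
#' dimensionality are promoted to 5D with singleton axes according to `axes`.
#'
#' @param data numeric array of non-negative intensities. A matrix is taken
#'   as a single (y, x) plane; higher-dimensional input needs `axes`.
#' @param geometry a [pixel_geometry()].
#' @param axes axis string naming the dimensions of `data` in order, e.g.
#'   `"yx"`, `"tyx"`, `"ctzyx"`; must end in `"yx"`. Ignored for 5D input.
#' @param normalized logical flag: values already scaled to \[0, 1\].
#' @param saturated optional logical array (same shape as `data`) flagging
#'   pixels at the detector's maximum representable value.
#' @return object of class `image_stack` with elements `data` (5D array),
#'   `geometry`, `normalized`, `saturated`.
#' @export
image_stack <- function(data, geometry, axes = NULL, normalized = FALSE,
                        saturated = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(1, 1, 1, dim(data)))
  else if (length(dim(data)) < 5L) {
    if (is.null(axes)) stop("axes must be given for non-matrix, non-5D data")
    data <- promote_axes(data, axes)
    if (!is.null(saturated)) saturated <- promote_axes(saturated, axes)
  }
  if (length(dim(data)) != 5L) stop("data must have 5 axes (t, c, z, y, x)")
  if (any(data < 0)) stop("image intensities must be non-negative")
  if (normalized && (min(data) < 0 || max(data) > 1))
    stop("normalized stacks must lie within [0, 1]")
  if (!inherits(geometry, "pixel_geometry")) stop("geometry must be a pixel_geometry")
  if (!is.null(saturated)) {
    if (is.matrix(saturated)) saturated <- array(saturated, dim = c(1, 1, 1, dim(saturated)))
    stopifnot(identical(dim(saturated), dim(data)))
  }
  structure(list(data = data, geometry = geometry, normalized = normalized,
                 saturated = saturated),
            class = "image_stack")
}

promote_axes <- function(data, axes) {
  ax <- strsplit(axes, "")[[1]]
  full <- c("t", "c", "z", "y", "x")
  if (!all(ax %in% full) || anyDuplicated(ax) ||
      !identical(tail_axes(ax), c("y", "x")))
    stop("axes must be a subset of 'tczyx' ending in 'yx'")
  if (is.null(dim(data)) || length(dim(data)) != length(ax))
    stop("data dimensionality does not match axes")
  if (is.unsorted(match(ax, full)))
    stop("axes must be given in t, c, z, y, x order")
  d <- rep(1L, 5)
  d[match(ax, full)] <- dim(data)
  # input axes are in tczyx order already (subset), so a plain reshape works
  array(data, dim = d)
}

tail_axes <- function(ax) ax[seq.int(max(1L, length(ax) - 1L), length(ax))]

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack (t=%d, c=%d, z=%d, y=%d, x=%d)%s, range [%g, %g]\n",
              d[1], d[2], d[3], d[4], d[5],
              if (x$normalized) ", normalized" else "",
              min(x$data), max(x$data)))
  print(x$geometry)
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Extract one (y, x) plane from a stack
#' @param stack an [image_stack()].
#' @param t,c,z 1-based frame, channel and plane indices.
#' @return numeric matrix (y, x).
#' @export
get_frame <- function(stack, t = 1, c = 1, z = 1) {
  stack$data[t, c, z, , , drop = TRUE]
}

set_frame <- function(stack, value, t = 1, c = 1, z = 1) {
  stack$data[t, c, z, , ] <- value
  stack
}

#' Binary region-of-interest mask
#'
#' @param mask logical matrix (y, x) or 3D array (z, y, x) aligned to a
#'   parent stack's spatial axes.
#' @param label short text label.
#' @param allow_empty permit an all-`FALSE` mask.
#' @export
roi_mask <- function(mask, label = "roi", allow_empty = FALSE) {
  mask <- mask > 0
  if (!allow_empty && !any(mask)) stop("ROI mask has no true pixels")
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' Read a TIFF file into an image stack
#'
#' Multi-page files are stacked along the axis named by `pages`; geometry is
#' taken from ImageJ-style TIFF metadata when present
#' (`unit=micron` + resolution tags, `finterval`, `spacing`), otherwise from
#' `geometry_override`.
#'
#' @param path path to a TIFF file.
#' @param geometry_override optional [pixel_geometry()] used when the file
#'   carries none (and taking precedence when given).
#' @param pages axis along which multiple pages are stacked: `"t"` or `"z"`.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, geometry_override = NULL, pages = c("t", "z")) {
  pages <- match.arg(pages)
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                   error = function(e) stop("unreadable TIFF: ", conditionMessage(e)))
  if (!is.list(imgs)) imgs <- list(imgs)
  sc_geom <- read_geometry_sidecar(path)
  geom <- geometry_override %||% sc_geom %||%
    parse_tiff_geometry(attributes(imgs[[1]]))
  if (is.null(geom))
    stop("missing geometry: no resolution metadata in file and no override given")
  planes <- lapply(imgs, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels of RGB pages
    p
  })
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  n <- length(planes)
  sc <- attr(sc_geom, "sidecar")
  if (!is.null(sc) && !is.null(sc$n_t) &&
      (sc$n_t %||% 1) * (sc$n_c %||% 1) * (sc$n_z %||% 1) == n) {
    arr <- array(0, dim = c(sc$n_t, sc$n_c, sc$n_z, ny, nx))
    i <- 0L
    for (t in seq_len(sc$n_t)) for (cc in seq_len(sc$n_c))
      for (z in seq_len(sc$n_z)) {
        i <- i + 1L
        arr[t, cc, z, , ] <- planes[[i]] * (sc$scale %||% 1)
      }
  } else {
    arr <- if (pages == "t") array(0, dim = c(n, 1, 1, ny, nx))
           else array(0, dim = c(1, 1, n, ny, nx))
    for (i in seq_len(n)) {
      if (pages == "t") arr[i, 1, 1, , ] <- planes[[i]]
      else arr[1, 1, i, , ] <- planes[[i]]
    }
  }
  image_stack(arr, geom)
}

parse_tiff_geometry <- function(info) {
  desc <- info$description %||% ""
  unit_um <- grepl("unit=micron", desc, fixed = TRUE)
  dx <- dy <- NULL
  if (unit_um && !is.null(info$x.resolution) && info$x.resolution > 0) {
    dx <- 1 / info$x.resolution
    dy <- if (!is.null(info$y.resolution) && info$y.resolution > 0)
      1 / info$y.resolution else dx
  }
  if (is.null(dx)) return(NULL)
  dt <- kv_num(desc, "finterval"); dz <- kv_num(desc, "spacing")
  pixel_geometry(dx, dy, dz = dz, dt = dt)
}

kv_num <- function(desc, key) {
  m <- regmatches(desc, regexpr(paste0(key, "=[0-9.eE+-]+"), desc))
  if (length(m) == 0) return(NULL)
  v <- as.numeric(sub(paste0(key, "="), "", m))
  if (is.finite(v) && v > 0) v else NULL
}

#' Write an image stack to a multi-page 32-bit float TIFF
#'
#' Pages are written in (t, c, z) order; the pixel geometry goes into a
#' JSON sidecar (`<path>.json`) that [read_stack()] reads back, so the
#' round trip preserves both raster and geometry. Values above 1 are
#' rescaled into \[0, 1\] for storage and scaled back on read via the
#' sidecar's `scale` field (the TIFF container stores normalized floats).
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  g <- stack$geometry
  d <- dim(stack$data)
  scale <- max(1, max(stack$data))
  planes <- list()
  for (t in seq_len(d[1])) for (cc in seq_len(d[2])) for (z in seq_len(d[3]))
    planes[[length(planes) + 1L]] <- stack$data[t, cc, z, , ] / scale
  tiff::writeTIFF(planes, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  jsonlite::write_json(
    list(dx = g$dx, dy = g$dy, dz = g$dz, dt = g$dt, scale = scale,
         axes = "tcz", n_t = d[1], n_c = d[2], n_z = d[3],
         normalized = stack$normalized),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_geometry_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  j <- jsonlite::read_json(sp, simplifyVector = TRUE)
  g <- pixel_geometry(j$dx, j$dy %||% j$dx, dz = j$dz, dt = j$dt)
  attr(g, "sidecar") <- j
  g
}

#' Per-frame robust normalization to \[0, 1\]
#'
#' Each (t, c, z) frame is mapped affinely so its `lo_pct` percentile goes to
#' 0 and its `hi_pct` percentile to 1, then clipped. Robust percentiles
#' (rather than min/max) make downstream fractional grey-level thresholds
#' insensitive to hot pixels. Percentiles use linear interpolation of the
#' sorted values. A degenerate frame (equal percentiles) becomes all zeros
#' and is recorded in the `degenerate` attribute.
#'
#' @param stack an [image_stack()].
#' @param lo_pct,hi_pct percentiles in \[0, 100\], `lo_pct < hi_pct`.
#' @return normalized [image_stack()]; attribute `degenerate` lists the
#'   (t, c, z) indices of degenerate frames.
#' @export
normalize_frames <- function(stack, lo_pct = 0.1, hi_pct = 99.9) {
  stopifnot(lo_pct >= 0, hi_pct <= 100, lo_pct < hi_pct)
  d <- dim(stack$data)
  out <- stack$data
  degenerate <- list()
  for (t in seq_len(d[1])) for (cc in seq_len(d[2])) for (z in seq_len(d[3])) {
    fr <- stack$data[t, cc, z, , ]
    q <- quantile(fr, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
    if (q[2] <= q[1]) {
      out[t, cc, z, , ] <- 0
      degenerate[[length(degenerate) + 1L]] <- c(t = t, c = cc, z = z)
    } else {
      out[t, cc, z, , ] <- pmin(1, pmax(0, (fr - q[1]) / (q[2] - q[1])))
    }
  }
  res <- image_stack(out, stack$geometry, normalized = TRUE,
                     saturated = stack$saturated)
  attr(res, "degenerate") <- degenerate
  res
}

#' Invert a normalized stack (v -> 1 - v)
#'
#' Shadow images show the extracellular space bright and cells dark;
#' inversion gives the conventional cells-bright view on which the
#' fractional grey-level thresholds are defined.
#'
#' @param stack a normalized [image_stack()].
#' @export
invert_stack <- function(stack) {
  if (!isTRUE(stack$normalized)) stop("invert_stack requires a normalized stack")
  image_stack(1 - stack$data, stack$geometry, normalized = TRUE,
              saturated = stack$saturated)
}

#' Read a binary mask from a single-page TIFF or PNG
#'
#' Non-zero pixels are `TRUE`.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param label mask label.
#' @export
read_roi_mask <- function(path, label = basename(path)) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  roi_mask(img > 0.5, label = label, allow_empty = TRUE)
}
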