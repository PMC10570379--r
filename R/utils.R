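`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bilinear interpolation on an image plane
#'
#' Samples an image at sub-pixel positions. Coordinates are 0-based and
#' pixel-centred: position (0, 0) is the centre of the top-left pixel and
#' physical position = index times pixel size. Exactly reproduces affine
#' intensity fields.
#'
#' @param img numeric matrix, indexed `img[y + 1, x + 1]`.
#' @param y,x numeric vectors of 0-based pixel coordinates.
#' @return numeric vector of interpolated values; `NA` outside the image.
#' @export
bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0;   fx <- x - x0
  # clamp the upper neighbour so points exactly on the last row/col work
  y1 <- pmin(y0 + 1, ny - 1); x1 <- pmin(x0 + 1, nx - 1)
  ok <- y >= 0 & x >= 0 & y <= ny - 1 & x <= nx - 1
  out <- rep(NA_real_, length(y))
  if (!any(ok)) return(out)
  i0 <- y0[ok] + 1; i1 <- y1[ok] + 1; j0 <- x0[ok] + 1; j1 <- x1[ok] + 1
  fyk <- fy[ok]; fxk <- fx[ok]
  v00 <- img[cbind(i0, j0)]; v01 <- img[cbind(i0, j1)]
  v10 <- img[cbind(i1, j0)]; v11 <- img[cbind(i1, j1)]
  out[ok] <- (1 - fyk) * ((1 - fxk) * v00 + fxk * v01) +
    fyk * ((1 - fxk) * v10 + fxk * v11)
  out
}

# 1D unit-sum Gaussian kernel for a given sigma in pixels; radius 4 sigma.
gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Paint an ellipse (axis-aligned radii in pixels, 0-based centre) into a
# logical matrix; returns linear indices of covered pixels.
ellipse_indices <- function(ny, nx, cy, cx, ry, rx) {
  ylo <- max(0, floor(cy - ry)); yhi <- min(ny - 1, ceiling(cy + ry))
  xlo <- max(0, floor(cx - rx)); xhi <- min(nx - 1, ceiling(cx + rx))
  if (ylo > yhi || xlo > xhi) return(integer(0))
  ys <- ylo:yhi; xs <- xlo:xhi
  d <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`)
  sub <- which(d <= 1, arr.ind = TRUE)
  if (nrow(sub) == 0) return(integer(0))
  (xs[sub[, 2]]) * ny + ys[sub[, 1]] + 1L
}
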