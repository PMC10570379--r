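# Small, fast phantom configurations for unit tests; acceptance tests use
# the full study-condition defaults.

small_lesion_config <- function(seed = 1, ...) {
  phantom_config(seed = seed,
                 lesion = modifyList(
                   list(n_cups = 10L, ny = 320L, nx = 320L, n_frames = 10L,
                        exact_counts = TRUE),
                   list(...)))
}

# Independent flood-fill-from-border oracle for hole pixels of a binary
# image: holes are background pixels not 4-connected to the border.
flood_fill_holes_oracle <- function(bin) {
  ny <- nrow(bin); nx <- ncol(bin)
  reach <- matrix(FALSE, ny, nx)
  q <- which(!bin & (row(bin) %in% c(1, ny) | col(bin) %in% c(1, nx)))
  reach[q] <- TRUE
  head_i <- 1L
  q <- as.integer(q)
  while (head_i <= length(q)) {
    cur <- q[head_i]; head_i <- head_i + 1L
    i <- (cur - 1L) %% ny + 1L; j <- (cur - 1L) %/% ny + 1L
    for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 >= 1 && i2 <= ny && j2 >= 1 && j2 <= nx) {
        k <- (j2 - 1L) * ny + i2
        if (!bin[k] && !reach[k]) { reach[k] <- TRUE; q <- c(q, k) }
      }
    }
  }
  !bin & !reach
}

# Paint an annulus (ring TRUE) into a logical matrix; 0-based centre px.
annulus_mask <- function(ny, nx, cy, cx, r_in, r_out) {
  d2 <- outer((seq_len(ny) - 1 - cy)^2, (seq_len(nx) - 1 - cx)^2, `+`)
  d2 <= r_out^2 & d2 > r_in^2
}

disk_mask <- function(ny, nx, cy, cx, r) {
  d2 <- outer((seq_len(ny) - 1 - cy)^2, (seq_len(nx) - 1 - cx)^2, `+`)
  d2 <= r^2
}

# Gaussian profile helper for constructing synthetic line profiles.
gauss_profile <- function(x, amp, mu, sigma, baseline = 0) {
  structure(list(positions = x,
                 values = baseline + amp * exp(-(x - mu)^2 / (2 * sigma^2)),
                 endpoints = rbind(c(0, 0), c(0, max(x))),
                 averaging_width = 1L, spacing = mean(diff(x))),
            class = "line_profile")
}
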