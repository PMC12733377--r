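# Fixtures are built in code; no binary files ship with the tests.

# A well-spread 6-point configuration for the quadratic design matrix. The
# points must not lie on any conic (e.g. corners + center + midpoint sit on
# the degenerate conic (x - y)(1 - x - y) = 0 and are rank deficient).
base_pts <- function(w = 100, h = 100) {
  data.frame(x = c(0, w, 0, w, w / 2, w / 5),
             y = c(0, 0, h, h, h / 4, 3 * h / 5))
}

identity_cp <- function(n_extra = 0, shape = c(100, 100), seed = 1) {
  p <- base_pts(shape[2], shape[1])
  if (n_extra > 0) {
    extra <- annotransfer:::with_local_seed(seed, data.frame(
      x = stats::runif(n_extra, 0, shape[2]),
      y = stats::runif(n_extra, 0, shape[1])))
    p <- rbind(p, extra)
  }
  control_points(data.frame(fixed_x = p$x, fixed_y = p$y,
                            moving_x = p$x, moving_y = p$y),
                 fixed_shape = shape, moving_shape = shape)
}

# Pairs generated by a known degree-2 transform on normalized coordinates:
# moving points scattered in the frame, fixed = t(moving).
cp_from_transform <- function(t, n = 12, shape = c(100, 100), seed = 1) {
  mv <- annotransfer:::with_local_seed(seed, cbind(
    stats::runif(n, 0.05, 0.95) * shape[2],
    stats::runif(n, 0.05, 0.95) * shape[1]))
  fx <- evaluate_transform(t, mv)
  control_points(data.frame(fixed_x = fx[, 1], fixed_y = fx[, 2],
                            moving_x = mv[, 1], moving_y = mv[, 2]),
                 fixed_shape = shape, moving_shape = shape)
}

# Random mild degree-2 transform (normalized units) between equal frames.
random_mild_transform <- function(seed, shape = c(100, 100), mag = 0.05) {
  annotransfer:::with_local_seed(seed, {
    a <- c(stats::runif(1, -mag / 4, mag / 4),
           1 + stats::runif(1, -mag / 2, mag / 2),
           stats::runif(1, -mag / 2, mag / 2),
           stats::runif(3, -mag, mag))
    b <- c(stats::runif(1, -mag / 4, mag / 4),
           stats::runif(1, -mag / 2, mag / 2),
           1 + stats::runif(1, -mag / 2, mag / 2),
           stats::runif(3, -mag, mag))
    poly_transform(a, b, normalization = "wh",
                   from_shape = shape, to_shape = shape)
  })
}

random_mask <- function(seed, nr = 16, nc = nr, p = 0.4) {
  annotransfer:::with_local_seed(seed,
    matrix(as.numeric(stats::runif(nr * nc) < p), nr, nc))
}

# Filled disc mask, 0-based center coordinates.
disc_mask <- function(shape, cx, cy, r) {
  dy <- matrix(0:(shape[1] - 1), shape[1], shape[2]) - cy
  dx <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE) - cx
  matrix(as.numeric(dx^2 + dy^2 <= r^2), shape[1], shape[2])
}

# Circle outline (1 px) as a mask, optionally with an angular gap.
circle_outline_mask <- function(shape, cx, cy, r, gap_at = NULL, gap_px = 0) {
  n <- ceiling(2 * pi * r * 4)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  if (!is.null(gap_at)) {
    half_ang <- (gap_px / 2) / r
    d <- abs(((th - gap_at + pi) %% (2 * pi)) - pi)
    th <- th[d > half_ang]
  }
  m <- matrix(0, shape[1], shape[2])
  xs <- round(cx + r * cos(th)); ys <- round(cy + r * sin(th))
  keep <- xs >= 0 & xs < shape[2] & ys >= 0 & ys < shape[1]
  m[cbind(ys[keep] + 1, xs[keep] + 1)] <- 1
  m
}

small_phantom <- function(seed, ...) {
  generate_phantom(phantom_params(seed = seed, shape = c(384, 384), ...))
}
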