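#' Second-order polynomial planar transform
#'
#' The registration model maps a point \eqn{(x, y)} in one image frame to
#' \eqn{(X, Y)} in the other through two degree-2 polynomials,
#' \deqn{X = a_0 + a_1 x + a_2 y + a_3 x^2 + a_4 x y + a_5 y^2,}
#' \deqn{Y = b_0 + b_1 x + b_2 y + b_3 x^2 + b_4 x y + b_5 y^2,}
#' which is flexible enough to absorb the local stretching, shrinking and
#' warping that formalin fixation and paraffin embedding impose on tissue,
#' while staying cheap to fit from a handful of hand-picked landmarks.
#'
#' A transform object records the twelve coefficients, the mapping
#' direction (`"moving_to_fixed"` maps raw fluorescence coordinates into the
#' H&E frame), the coordinate normalization convention, and the shapes of
#' the two frames so pixel coordinates can be normalized and de-normalized
#' transparently. With `normalization = "none"` the polynomials act on raw
#' coordinates, which is how printed coefficient sets on unit-scale
#' coordinates are evaluated.
#'
#' @param a,b Numeric vectors of six finite coefficients each, ordered as
#'   constant, x, y, x^2, xy, y^2.
#' @param direction `"moving_to_fixed"` or `"fixed_to_moving"`.
#' @param normalization `"wh"` (x by width, y by height), `"max"` (both by
#'   the maximum dimension) or `"none"`.
#' @param from_shape,to_shape `c(rows, cols)` of the input-side and
#'   output-side frames; required unless `normalization = "none"`.
#' @return An object of class `poly_transform`.
#' @seealso [fit_transform()], [evaluate_transform()], [warp_image()]
#' @examples
#' ident <- poly_transform(c(0, 1, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0),
#'                         normalization = "none")
#' evaluate_transform(ident, cbind(0.3, 0.7))
#' @export
poly_transform <- function(a, b,
                           direction = c("moving_to_fixed", "fixed_to_moving"),
                           normalization = c("wh", "max", "none"),
                           from_shape = NULL, to_shape = NULL) {
  direction <- match.arg(direction)
  normalization <- match.arg(normalization)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 6 || length(b) != 6 || any(!is.finite(c(a, b)))) {
    stop("`a` and `b` must each hold six finite coefficients", call. = FALSE)
  }
  if (normalization != "none") {
    if (is.null(from_shape) || is.null(to_shape)) {
      stop("`from_shape` and `to_shape` are required unless normalization is 'none'",
           call. = FALSE)
    }
    check_shape_arg(from_shape, "from_shape")
    check_shape_arg(to_shape, "to_shape")
    from_shape <- as.integer(from_shape[1:2])
    to_shape <- as.integer(to_shape[1:2])
  }
  structure(list(a = a, b = b, direction = direction,
                 normalization = normalization,
                 from_shape = from_shape, to_shape = to_shape),
            class = "poly_transform")
}

poly_basis <- function(p) {
  cbind(1, p[, 1], p[, 2], p[, 1]^2, p[, 1] * p[, 2], p[, 2]^2)
}

#' Apply a polynomial transform to points
#'
#' Maps points given in the transform's input frame (pixels, unless the
#' transform carries no normalization) to the output frame.
#'
#' @param t A [poly_transform()].
#' @param p Two-column matrix or data frame of `(x, y)` coordinates.
#' @return A two-column matrix of transformed coordinates.
#' @export
evaluate_transform <- function(t, p) {
  stopifnot(inherits(t, "poly_transform"))
  p <- as_xy_matrix(p)
  if (t$normalization != "none") {
    p <- normalize_points(p, t$from_shape, t$normalization)
  }
  d <- poly_basis(p)
  out <- cbind(x = as.vector(d %*% t$a), y = as.vector(d %*% t$b))
  if (t$normalization != "none") {
    out <- denormalize_points(out, t$to_shape, t$normalization)
  }
  out
}

#' Fit the degree-2 registration transform from paired landmarks
#'
#' Estimates the twelve polynomial coefficients by per-axis linear least
#' squares on the quadratic design matrix `[1, x, y, x^2, xy, y^2]` of the
#' normalized input-side points. The system is solved with a pivoted
#' (rank-revealing) QR decomposition rather than normal equations, and a
#' near-rank-deficient landmark configuration — which would extrapolate
#' wildly — is a hard error governed by `condition_cap`. With exactly six
#' non-degenerate pairs the fit interpolates every landmark.
#'
#' @param points A [control_points()] object.
#' @param direction `"moving_to_fixed"` (default) fits the map from raw
#'   fluorescence coordinates to H&E coordinates; `"fixed_to_moving"` swaps
#'   the roles (the inverse-mapping convention used to warp images).
#' @param normalization Coordinate normalization convention, see
#'   [poly_transform()].
#' @param condition_cap Maximum accepted 2-norm condition number of the
#'   normalized design matrix (default `1e8`).
#' @return A `poly_transform` whose attributes carry the fit diagnostics:
#'   `residuals` (per-pair output-frame distance, pixels), `rms` (their root
#'   mean square) and `condition`. [generics::tidy()] and
#'   [generics::glance()] expose them as tibbles.
#' @export
fit_transform <- function(points,
                          direction = c("moving_to_fixed", "fixed_to_moving"),
                          normalization = c("wh", "max"),
                          condition_cap = 1e8) {
  direction <- match.arg(direction)
  normalization <- match.arg(normalization)
  stopifnot(inherits(points, "control_points"))
  check_min_pairs(points)
  fixed_shape <- attr(points, "fixed_shape")
  moving_shape <- attr(points, "moving_shape")
  if (direction == "moving_to_fixed") {
    from <- cbind(points$moving_x, points$moving_y); from_shape <- moving_shape
    to <- cbind(points$fixed_x, points$fixed_y);     to_shape <- fixed_shape
  } else {
    from <- cbind(points$fixed_x, points$fixed_y);   from_shape <- fixed_shape
    to <- cbind(points$moving_x, points$moving_y);   to_shape <- moving_shape
  }
  fn <- normalize_points(from, from_shape, normalization)
  tn <- normalize_points(to, to_shape, normalization)
  d <- poly_basis(fn)
  cond <- kappa(d, exact = TRUE)
  if (!is.finite(cond) || cond > condition_cap) {
    stop(sprintf(paste0(
      "landmark configuration is numerically degenerate: design-matrix ",
      "condition number %.3g exceeds the cap %.3g; spread the points (avoid ",
      "collinear or clustered landmarks)"), cond, condition_cap), call. = FALSE)
  }
  qrd <- qr(d, LAPACK = TRUE)
  coefs <- qr.coef(qrd, tn)
  t <- poly_transform(coefs[, 1], coefs[, 2], direction = direction,
                      normalization = normalization,
                      from_shape = from_shape, to_shape = to_shape)
  pred <- evaluate_transform(t, from)
  res <- sqrt(rowSums((pred - denormalize_points(tn, to_shape, normalization))^2))
  attr(t, "residuals") <- res
  attr(t, "rms") <- sqrt(mean(res^2))
  attr(t, "condition") <- cond
  attr(t, "n_pairs") <- nrow(points)
  t
}

#' @describeIn fit_transform Fit the inverse mapping by swapping the
#'   fixed/moving roles of the landmarks (a degree-2 polynomial has no
#'   closed-form inverse; refitting on swapped roles is the stable way to
#'   inverse-register the refined annotation).
#' @export
fit_inverse_transform <- function(points, normalization = c("wh", "max"),
                                  condition_cap = 1e8) {
  fit_transform(points, direction = "fixed_to_moving",
                normalization = match.arg(normalization),
                condition_cap = condition_cap)
}

#' @export
print.poly_transform <- function(x, ...) {
  cat(sprintf("<poly_transform %s, normalization '%s'>\n", x$direction,
              x$normalization))
  cat("  a:", paste(formatC(x$a, digits = 6, format = "g"), collapse = " "), "\n")
  cat("  b:", paste(formatC(x$b, digits = 6, format = "g"), collapse = " "), "\n")
  if (!is.null(attr(x, "rms"))) {
    cat(sprintf("  fit: %d pairs, RMS residual %.4g px, condition %.3g\n",
                attr(x, "n_pairs"), attr(x, "rms"), attr(x, "condition")))
  }
  invisible(x)
}

#' Tidy a fitted polynomial transform
#'
#' @param x A `poly_transform`.
#' @param ... Unused.
#' @return `tidy()` gives one row per coefficient (`axis`, `term`,
#'   `estimate`); `glance()` a one-row fit summary.
#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.poly_transform <- function(x, ...) {
  terms <- c("1", "x", "y", "x^2", "xy", "y^2")
  tibble::tibble(
    axis = rep(c("x", "y"), each = 6),
    term = rep(terms, 2),
    coefficient = rep(c("a", "b"), each = 6),
    order = rep(0:5, 2),
    estimate = c(x$a, x$b))
}

#' @rdname tidy.poly_transform
#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.poly_transform <- function(x, ...) {
  tibble::tibble(
    direction = x$direction,
    normalization = x$normalization,
    n_pairs = attr(x, "n_pairs") %||% NA_integer_,
    rms_px = attr(x, "rms") %||% NA_real_,
    max_residual_px = if (is.null(attr(x, "residuals"))) NA_real_
                      else max(attr(x, "residuals")),
    condition = attr(x, "condition") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a transform to JSON (and back)
#'
#' Writes the coefficients at full double precision together with the
#' direction and normalization metadata, so a read-back reproduces the
#' written decimal representation exactly.
#'
#' @param t A `poly_transform`.
#' @param path Output (input) JSON path.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "poly_transform"))
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(list(
    a = t$a, b = t$b, direction = t$direction,
    normalization = t$normalization,
    from_shape = t$from_shape, to_shape = t$to_shape),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::fromJSON(path)
  poly_transform(j$a, j$b, direction = j$direction,
                 normalization = j$normalization,
                 from_shape = j$from_shape, to_shape = j$to_shape)
}
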