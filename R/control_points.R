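#' Paired registration landmarks
#'
#' A `control_points` object is a tibble with columns `fixed_x`, `fixed_y`,
#' `moving_x`, `moving_y` (pixel units, 0-based, x = column, y = row) plus
#' the shapes of the two images the coordinates live in. Fixed points come
#' from the annotated H&E image, moving points from the raw fluorescence
#' (e.g. MUSE) image. At least six distinct pairs are required to determine
#' the twelve coefficients of the degree-2 polynomial transform.
#'
#' @param pairs A data frame with columns `fixed_x`, `fixed_y`, `moving_x`,
#'   `moving_y` in pixel coordinates.
#' @param fixed_shape,moving_shape Integer vectors `c(rows, cols)` giving the
#'   dimensions of the fixed (H&E) and moving (fluorescence) images; used to
#'   normalize coordinates before fitting.
#' @return A tibble of class `control_points` with attributes `fixed_shape`
#'   and `moving_shape`. Exact duplicate pairs are dropped.
#' @examples
#' cp <- control_points(
#'   data.frame(fixed_x = c(0, 100, 0, 100, 50, 25),
#'              fixed_y = c(0, 0, 100, 100, 50, 75),
#'              moving_x = c(2, 102, 2, 102, 52, 27),
#'              moving_y = c(1, 1, 101, 101, 51, 76)),
#'   fixed_shape = c(128, 128), moving_shape = c(128, 128))
#' nrow(cp)
#' @export
control_points <- function(pairs, fixed_shape, moving_shape) {
  cols <- c("fixed_x", "fixed_y", "moving_x", "moving_y")
  if (!all(cols %in% names(pairs))) {
    stop("`pairs` must have columns fixed_x, fixed_y, moving_x, moving_y",
         call. = FALSE)
  }
  pairs <- tibble::as_tibble(pairs)[cols]
  if (!all(vapply(pairs, is.numeric, logical(1))) ||
      !all(vapply(pairs, function(v) all(is.finite(v)), logical(1)))) {
    stop("control point coordinates must be finite numbers", call. = FALSE)
  }
  pairs <- dplyr::distinct(pairs)
  check_shape_arg(fixed_shape, "fixed_shape")
  check_shape_arg(moving_shape, "moving_shape")
  check_min_pairs(pairs)
  structure(pairs,
            fixed_shape = as.integer(fixed_shape[1:2]),
            moving_shape = as.integer(moving_shape[1:2]),
            class = c("control_points", class(pairs)))
}

check_shape_arg <- function(shape, arg) {
  if (length(shape) < 2 || any(!is.finite(shape[1:2])) || any(shape[1:2] <= 0)) {
    stop(sprintf("`%s` must be positive c(rows, cols)", arg), call. = FALSE)
  }
  invisible(NULL)
}

check_min_pairs <- function(pairs) {
  if (nrow(pairs) < 6) {
    stop(sprintf(paste0(
      "only %d distinct control point pair(s); at least six pairs of ",
      "corresponding points are required to fit the second-order polynomial ",
      "transform"), nrow(pairs)), call. = FALSE)
  }
  invisible(NULL)
}

#' Normalize pixel coordinates to unit scale
#'
#' Divides x by the image width and y by the image height (convention
#' `"wh"`), or both by the maximum dimension (`"max"`), so that the
#' quadratic design matrix of the polynomial fit stays well conditioned at
#' slide scales. [denormalize_points()] inverts the operation.
#'
#' @param p A two-column matrix or data frame of `(x, y)` pixel coordinates.
#' @param shape `c(rows, cols)` of the reference image.
#' @param normalization `"wh"` (default) or `"max"`.
#' @return A two-column numeric matrix of dimensionless coordinates.
#' @export
normalize_points <- function(p, shape, normalization = c("wh", "max")) {
  normalization <- match.arg(normalization)
  check_shape_arg(shape, "shape")
  p <- as_xy_matrix(p)
  div <- norm_divisors(shape, normalization)
  cbind(x = p[, 1] / div[1], y = p[, 2] / div[2])
}

#' @rdname normalize_points
#' @export
denormalize_points <- function(p, shape, normalization = c("wh", "max")) {
  normalization <- match.arg(normalization)
  check_shape_arg(shape, "shape")
  p <- as_xy_matrix(p)
  div <- norm_divisors(shape, normalization)
  cbind(x = p[, 1] * div[1], y = p[, 2] * div[2])
}

norm_divisors <- function(shape, normalization) {
  if (normalization == "wh") c(shape[2], shape[1])
  else rep(max(shape[1:2]), 2)
}

as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  if (ncol(p) != 2) stop("points must have two columns (x, y)", call. = FALSE)
  storage.mode(p) <- "double"
  if (any(!is.finite(p))) stop("point coordinates must be finite", call. = FALSE)
  p
}

#' Read or write a control point file
#'
#' The interchange format is a CSV with header
#' `fixed_x,fixed_y,moving_x,moving_y` (pixel units) or a JSON array of
#' objects with the same keys. Fewer than six rows is rejected because the
#' degree-2 fit is underdetermined below that.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @param fixed_shape,moving_shape Image shapes attached to the returned
#'   [control_points()] object.
#' @return `read_points()` returns a `control_points` tibble;
#'   `write_points()` returns `path` invisibly.
#' @export
read_points <- function(path, fixed_shape, moving_shape) {
  if (!file.exists(path)) stop(sprintf("points file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") read_points_json(path) else read_points_csv(path)
  control_points(df, fixed_shape, moving_shape)
}

read_points_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty control point file", call. = FALSE)
  header <- trimws(strsplit(lines[1], ",")[[1]])
  expect <- c("fixed_x", "fixed_y", "moving_x", "moving_y")
  if (!identical(header, expect)) {
    stop(sprintf("line 1: expected header '%s', got '%s'",
                 paste(expect, collapse = ","), lines[1]), call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- trimws(strsplit(lines[i], ",")[[1]])
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 4 || any(is.na(v))) {
      stop(sprintf("line %d: expected four numeric fields, got '%s'", i, lines[i]),
           call. = FALSE)
    }
    v
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- expect
  df
}

read_points_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (!is.data.frame(df)) df <- as.data.frame(df)
  df
}

#' @rdname read_points
#' @param points A `control_points` object (or a data frame with the four
#'   coordinate columns).
#' @export
write_points <- function(points, path) {
  cols <- c("fixed_x", "fixed_y", "moving_x", "moving_y")
  df <- as.data.frame(points)[cols]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Jitter the moving-side landmarks
#'
#' Adds independent zero-mean Gaussian displacement (standard deviation
#' `sigma`, pixels) to the moving points only, emulating the error a human
#' makes when clicking corresponding landmarks. Fixed points are untouched;
#' `sigma = 0` returns the input unchanged.
#'
#' @param points A [control_points()] object.
#' @param sigma Displacement standard deviation in pixels, per axis.
#' @param seed Integer seed for the jitter draw (mandatory; the global RNG
#'   state is left untouched).
#' @return A `control_points` object with perturbed moving coordinates.
#' @export
perturb_control_points <- function(points, sigma, seed) {
  stopifnot(inherits(points, "control_points"))
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (sigma == 0) return(points)
  n <- nrow(points)
  d <- with_local_seed(seed, matrix(stats::rnorm(2 * n, sd = sigma), ncol = 2))
  out <- points
  out$moving_x <- points$moving_x + d[, 1]
  out$moving_y <- points$moving_y + d[, 2]
  control_points(as.data.frame(out), attr(points, "fixed_shape"),
                 attr(points, "moving_shape"))
}
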