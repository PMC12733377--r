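#' Dice similarity coefficient
#'
#' Area overlap between two binary masks,
#' \deqn{DSC = 2 |I_1 \cap I_2| / (|I_1| + |I_2|),}
#' 1 for perfect overlap and 0 for none. Computed on filled region masks,
#' not outlines. Convention for degenerate inputs (flagged in reports): two
#' empty masks agree perfectly (1.0); one empty mask scores 0.0.
#'
#' @param i1,i2 0/1 matrices of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(i1, i2) {
  check_binary(i1, "i1"); check_binary(i2, "i2")
  check_same_shape(i1, i2, "masks")
  s1 <- sum(i1); s2 <- sum(i2)
  if (s1 + s2 == 0) return(1.0)
  2 * sum(i1 * i2) / (s1 + s2)
}

#' Hausdorff distance between annotation outlines
#'
#' The symmetric Hausdorff distance
#' \deqn{H = \max\{\sup_a \inf_b d(a,b),\; \sup_b \inf_a d(a,b)\}}
#' with Euclidean pixel distance, i.e. the worst boundary deviation between
#' the two outlines. Because sample image sizes vary, the reported value is
#' normalized by the maximum image dimension (set `normalize = FALSE` for
#' raw pixels). A directed variant is available behind `directed`.
#'
#' @param o1,o2 Outlines from [boundary_of()] or two-column `(x, y)` tables;
#'   both non-empty.
#' @param shape `c(rows, cols)` of the shared reference image; defaults to
#'   the outlines' own shape attribute.
#' @param normalize Divide by `max(shape)` (default `TRUE`).
#' @param directed `"none"` (symmetric, default), `"1to2"` or `"2to1"`.
#' @return The (normalized) Hausdorff distance.
#' @export
hausdorff_distance <- function(o1, o2, shape = NULL, normalize = TRUE,
                               directed = c("none", "1to2", "2to1")) {
  directed <- match.arg(directed)
  p1 <- as_xy_matrix(as.data.frame(o1)[, c("x", "y")])
  p2 <- as_xy_matrix(as.data.frame(o2)[, c("x", "y")])
  if (nrow(p1) == 0 || nrow(p2) == 0) {
    stop("Hausdorff distance is undefined for an empty outline", call. = FALSE)
  }
  if (is.null(shape)) shape <- outline_shape(o1) %||% outline_shape(o2)
  if (normalize && is.null(shape)) {
    stop("`shape` is required to normalize the distance", call. = FALSE)
  }
  d12 <- directed_sup(p1, p2)
  h <- switch(directed,
              none = max(d12, directed_sup(p2, p1)),
              `1to2` = d12,
              `2to1` = directed_sup(p2, p1))
  if (normalize) h / max(shape[1:2]) else h
}

# sup over a of the distance to the nearest b, chunked to bound memory
directed_sup <- function(a, b, chunk = 2048L) {
  worst <- 0
  for (i in seq(1, nrow(a), by = chunk)) {
    ai <- a[i:min(i + chunk - 1, nrow(a)), , drop = FALSE]
    d2 <- outer(ai[, 1], b[, 1], "-")^2 + outer(ai[, 2], b[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

#' Feature-space cosine similarity between two images
#'
#' Compares two images through the cosine similarity of feature vectors
#' produced by a pluggable extractor — any deterministic function mapping an
#' image to a fixed-length numeric vector. Identical images score exactly 1
#' for every conforming extractor. The built-in descriptor
#' ([extractor_builtin()]) is fully offline; an adapter for a pretrained
#' convolutional network (e.g. an AlexNet fully-connected layer, as used for
#' the published similarity scores) can be supplied through the same
#' contract when approximating those values matters.
#'
#' @param img1,img2 Image arrays.
#' @param extractor A feature extractor; see [extractor_builtin()].
#' @return Cosine similarity in `[-1, 1]`.
#' @export
feature_similarity <- function(img1, img2, extractor = extractor_builtin()) {
  f <- extractor_fun(extractor)
  v1 <- as.numeric(f(img1)); v2 <- as.numeric(f(img2))
  if (length(v1) != length(v2)) {
    stop("extractor returned vectors of different lengths", call. = FALSE)
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop(sprintf("extractor '%s' produced a zero-norm feature vector",
                 extractor_id(extractor)), call. = FALSE)
  }
  sum(v1 * v2) / (n1 * n2)
}

#' Built-in offline feature extractor
#'
#' A deterministic, training-free image descriptor: the image is resized to
#' a fixed grid, then described by coarse multiscale block-mean intensities
#' per channel plus gradient-orientation histograms (8 bins over 4x4 cells)
#' of the grayscale image — a classic handcrafted stand-in for deep
#' features, adequate for self-consistency checks and relative comparisons.
#'
#' @param size Resize target in pixels (square), default 64.
#' @return An object usable as the `extractor` argument of
#'   [feature_similarity()]. Any plain function `image -> numeric vector`
#'   also satisfies the contract.
#' @export
extractor_builtin <- function(size = 64) {
  f <- function(img) {
    if (n_channels(img) == 1) img <- array(rep(img, 3), c(dim(img), 3))
    r <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
                         w = size, h = size)
    arr <- aperm(EBImage::imageData(r), c(2, 1, 3))
    block <- function(m, nb) {
      idx <- cut(seq_len(nrow(m)) - 1, nb, labels = FALSE)
      jdx <- cut(seq_len(ncol(m)) - 1, nb, labels = FALSE)
      as.vector(tapply(m, list(idx[row(m)], jdx[col(m)]), mean))
    }
    means <- unlist(lapply(1:3, function(k) c(block(arr[, , k], 4), block(arr[, , k], 8))))
    g <- to_grayscale(arr)
    gx <- shift_matrix(g, 0, -1) - shift_matrix(g, 0, 1)
    gy <- shift_matrix(g, -1, 0) - shift_matrix(g, 1, 0)
    mag <- sqrt(gx^2 + gy^2)
    ang <- (atan2(gy, gx) + pi) / (2 * pi)          # [0, 1)
    bin <- pmin(floor(ang * 8), 7)
    cell_i <- cut(seq_len(nrow(g)) - 1, 4, labels = FALSE)
    cell_j <- cut(seq_len(ncol(g)) - 1, 4, labels = FALSE)
    key <- (cell_i[row(g)] - 1) * 32 + (cell_j[col(g)] - 1) * 8 + bin
    hist <- vapply(0:127, function(k) sum(mag[key == k]), numeric(1))
    c(means, hist)
  }
  structure(f, id = sprintf("builtin-multiscale-%d", size),
            class = c("feature_extractor", "function"))
}

extractor_fun <- function(x) {
  if (!is.function(x)) stop("`extractor` must be a function image -> numeric vector",
                            call. = FALSE)
  x
}

extractor_id <- function(x) attr(x, "id") %||% "custom"

#' Three-metric agreement report for one sample
#'
#' Evaluates a semi-automatically transferred annotation against a manual
#' reference with the Dice coefficient on the filled masks, the normalized
#' symmetric Hausdorff distance on their boundaries, and (when the two
#' annotated images are supplied) the feature-space cosine similarity.
#'
#' @param semi_mask,manual_mask 0/1 masks of equal shape.
#' @param semi_img,manual_img Optional annotated images for the feature
#'   similarity term.
#' @param extractor Feature extractor, see [feature_similarity()].
#' @param sample_id Label carried into the report.
#' @return A one-row tibble of class `similarity_report` with columns
#'   `sample_id`, `dsc`, `feature_similarity`, `hausdorff_normalized`,
#'   `extractor_id` and the degenerate-mask flag `empty_mask`.
#' @export
evaluate_transfer <- function(semi_mask, manual_mask, semi_img = NULL,
                              manual_img = NULL, extractor = extractor_builtin(),
                              sample_id = NA_character_) {
  check_binary(semi_mask, "semi_mask"); check_binary(manual_mask, "manual_mask")
  check_same_shape(semi_mask, manual_mask, "masks")
  d <- dice(semi_mask, manual_mask)
  h <- if (sum(semi_mask) > 0 && sum(manual_mask) > 0) {
    hausdorff_distance(boundary_of(semi_mask), boundary_of(manual_mask),
                       shape = dim(semi_mask))
  } else NA_real_
  fs <- if (!is.null(semi_img) && !is.null(manual_img)) {
    feature_similarity(semi_img, manual_img, extractor)
  } else NA_real_
  out <- tibble::tibble(
    sample_id = sample_id, dsc = d, feature_similarity = fs,
    hausdorff_normalized = h,
    extractor_id = if (is.na(fs)) NA_character_ else extractor_id(extractor),
    empty_mask = sum(semi_mask) == 0 || sum(manual_mask) == 0)
  class(out) <- c("similarity_report", class(out))
  out
}

#' Batch summary of similarity reports
#'
#' Order statistics per metric in the layout of a boxplot table: minimum,
#' 25th percentile, median, 75th percentile, maximum, and the values falling
#' outside the 1.5 x IQR whiskers. Quantiles use linear interpolation
#' between order statistics (R type 7), so e.g. the quartiles of 1..100 are
#' 25.75 and 75.25.
#'
#' @param reports A tibble of stacked [evaluate_transfer()] rows (or any
#'   data frame with `dsc`, `feature_similarity`, `hausdorff_normalized`).
#' @return A tibble with one row per metric and a list-column `outliers`.
#' @export
summarize_batch <- function(reports) {
  if (nrow(reports) == 0) stop("empty batch", call. = FALSE)
  metrics <- c("dsc", "feature_similarity", "hausdorff_normalized")
  rows <- lapply(metrics, function(m) {
    v <- reports[[m]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(tibble::tibble(metric = m, n = 0L, min = NA_real_, q25 = NA_real_,
                            median = NA_real_, q75 = NA_real_, max = NA_real_,
                            outliers = list(numeric(0))))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    tibble::tibble(metric = m, n = length(v), min = min(v), q25 = q[1],
                   median = q[2], q75 = q[3], max = max(v),
                   outliers = list(sort(out)))
  })
  dplyr::bind_rows(rows)
}
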