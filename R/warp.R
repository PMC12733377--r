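#' Warp an image through a polynomial transform
#'
#' Resamples `img` onto the grid of the transform's *input* frame using the
#' inverse-mapping convention: for every output pixel `p`, the transform is
#' evaluated to find the location `t(p)` in `img` (the transform's output
#' frame) and the image is sampled there. To register a raw fluorescence
#' image into the H&E frame you therefore pass the `"fixed_to_moving"` fit;
#' to carry a refined H&E-space mask back into raw fluorescence space you
#' pass the `"moving_to_fixed"` fit. Passing a transform whose output frame
#' does not match `img` is a hard error — it almost always means the
#' direction flag is wrong.
#'
#' @param img Matrix (grayscale/mask) or rows x cols x channels array.
#' @param t A [poly_transform()] fitted with normalization; its `to_shape`
#'   must equal the shape of `img`.
#' @param out_shape `c(rows, cols)` of the output canvas; defaults to the
#'   transform's input-frame shape. Coordinate normalization always uses the
#'   shapes bound to the transform, so enlarging the canvas only extends the
#'   field of view.
#' @param interpolation `"bilinear"` (images) or `"nearest"` (masks; the
#'   only choice that keeps a binary input binary).
#' @param fill Value for samples falling outside `img` (default 0: dark
#'   background in both modalities).
#' @return The warped image, same channel count as `img`.
#' @export
warp_image <- function(img, t, out_shape = NULL,
                       interpolation = c("bilinear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(t, "poly_transform"))
  if (t$normalization == "none") {
    stop("warping needs a transform fitted with coordinate normalization",
         call. = FALSE)
  }
  in_shape <- img_shape(img)
  if (!identical(as.integer(in_shape), t$to_shape)) {
    stop(sprintf(paste0(
      "transform direction mismatch: `img` is %s but the transform samples ",
      "its output frame of shape %s; pass the transform fitted in the ",
      "opposite direction"),
      paste(in_shape, collapse = "x"), paste(t$to_shape, collapse = "x")),
      call. = FALSE)
  }
  if (is.null(out_shape)) out_shape <- t$from_shape
  nr <- as.integer(out_shape[1]); nc <- as.integer(out_shape[2])
  # 0-based coordinates of every output pixel, column-major like R matrices
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  src <- evaluate_transform(t, cbind(xs, ys))
  nch <- n_channels(img)
  get_channel <- function(k) if (nch == 1) img else img[, , k]
  sample_one <- function(ch) {
    if (interpolation == "nearest") {
      xi <- round(src[, 1]); yi <- round(src[, 2])
      ok <- xi >= 0 & xi <= nc_in - 1 & yi >= 0 & yi <= nr_in - 1
      v <- rep(fill, length(xi))
      v[ok] <- ch[cbind(yi[ok] + 1, xi[ok] + 1)]
      v
    } else {
      x0 <- floor(src[, 1]); y0 <- floor(src[, 2])
      fx <- src[, 1] - x0; fy <- src[, 2] - y0
      v <- rep(fill, length(x0))
      ok <- x0 >= -1 & x0 <= nc_in - 1 & y0 >= -1 & y0 <= nr_in - 1
      gather <- function(yy, xx) {
        inb <- yy >= 0 & yy <= nr_in - 1 & xx >= 0 & xx <= nc_in - 1
        g <- rep(fill, length(xx))
        g[inb] <- ch[cbind(yy[inb] + 1, xx[inb] + 1)]
        g
      }
      v00 <- gather(y0, x0);     v01 <- gather(y0, x0 + 1)
      v10 <- gather(y0 + 1, x0); v11 <- gather(y0 + 1, x0 + 1)
      out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
             fy * ((1 - fx) * v10 + fx * v11)
      v[ok] <- out[ok]
      v
    }
  }
  nr_in <- in_shape[1]; nc_in <- in_shape[2]
  if (nch == 1) {
    matrix(sample_one(get_channel(1)), nr, nc)
  } else {
    out <- array(0, c(nr, nc, nch))
    for (k in seq_len(nch)) out[, , k] <- matrix(sample_one(get_channel(k)), nr, nc)
    out
  }
}

#' Registration quality as mask overlap
#'
#' Dice coefficient between the tissue mask of the warped fluorescence image
#' and the tissue mask of the fixed image — the score a user maximizes while
#' iteratively refining the manually picked landmark pairs.
#'
#' @param warped_tissue_mask,fixed_tissue_mask Binary masks of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
registration_quality <- function(warped_tissue_mask, fixed_tissue_mask) {
  dice(warped_tissue_mask, fixed_tissue_mask)
}
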