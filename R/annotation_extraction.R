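#' Recover the drawn annotation outline by image subtraction
#'
#' The pathologist's outline is obtained from two exports of the same H&E
#' field — one with the annotation overlay burned in and one without — by
#' flagging every pixel whose maximum per-channel absolute difference
#' exceeds `diff_threshold`. Subtraction is color-agnostic: no assumption is
#' made about the stroke color.
#'
#' @param annotated,clean Same-shape, same-channel-count images in `[0, 1]`.
#' @param diff_threshold Difference level above which a pixel counts as part
#'   of the overlay. Default `10/255`, which absorbs the small everywhere-
#'   nonzero differences JPEG compression introduces between the exports.
#' @return A 0/1 matrix marking the drawn outline pixels.
#' @export
subtract_annotation_layer <- function(annotated, clean, diff_threshold = 10 / 255) {
  if (!identical(dim(annotated), dim(clean))) {
    stop("annotated and clean exports must have identical shape and channels",
         call. = FALSE)
  }
  if (diff_threshold < 0 || diff_threshold > 1) {
    stop("`diff_threshold` must lie in the pixel range [0, 1]", call. = FALSE)
  }
  d <- abs(annotated - clean)
  if (length(dim(d)) == 3) d <- apply(d, c(1, 2), max)
  out <- matrix(as.numeric(d > diff_threshold), nrow(d), ncol(d))
  out
}

#' Morphologically close an annotation outline
#'
#' Hand-drawn outlines exported at reduced resolution are rarely fully
#' closed curves; closing with a disc structuring element bridges gaps up to
#' roughly the element width so the subsequent fill sees one closed contour.
#'
#' @param outline 0/1 matrix.
#' @param radius Disc radius in pixels (element width `2*radius + 1`);
#'   default 5, a few times a typical stroke width.
#' @return Closed 0/1 matrix; always a superset of the input.
#' @export
close_outline <- function(outline, radius = 5) {
  check_binary(outline, "outline")
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  if (sum(outline) == 0) return(outline)
  k <- disc_brush(2L * as.integer(radius) + 1L)
  closed <- EBImage::closing(outline, k)
  # closing is extensive only away from the frame border; re-union keeps the
  # superset property everywhere
  m <- pmax(as_storage_matrix(closed), outline)
  m
}

#' Fill the interior of closed outlines
#'
#' Every hole enclosed by the (closed) outline becomes foreground; pixels
#' connected to the border background stay background. Multiple disjoint
#' outlines are all filled. Foreground is treated 8-connected (background
#' 4-connected), avoiding the usual fill/boundary topology paradoxes.
#'
#' @param closed_outline 0/1 matrix.
#' @return Filled 0/1 matrix; superset of the input.
#' @export
fill_outline <- function(closed_outline) {
  check_binary(closed_outline, "closed_outline")
  if (sum(closed_outline) == 0) return(closed_outline)
  filled <- EBImage::fillHull(closed_outline)
  as_storage_matrix(filled)
}

#' Extract the annotation mask from the H&E export pair
#'
#' Composition of [subtract_annotation_layer()], [close_outline()] and
#' [fill_outline()]: the filled region the pathologist's outline encloses.
#' At this stage the mask may legitimately overhang the tissue into
#' background (pathologists include background that might hold tumor in
#' deeper sections); the refinement step removes it later.
#'
#' @inheritParams subtract_annotation_layer
#' @param closing_radius Disc radius for [close_outline()].
#' @return A 0/1 annotation mask. If the two exports are identical an empty
#'   mask is returned with a warning.
#' @export
extract_annotation_mask <- function(annotated, clean, diff_threshold = 10 / 255,
                                    closing_radius = 5) {
  outline <- subtract_annotation_layer(annotated, clean, diff_threshold)
  if (sum(outline) == 0) {
    warning("annotated and clean exports are identical above the difference threshold; empty annotation mask")
    return(outline)
  }
  fill_outline(close_outline(outline, closing_radius))
}
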