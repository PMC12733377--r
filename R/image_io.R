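#' Read and write raster images
#'
#' Images are held as base-R numeric arrays of shape rows x cols (grayscale)
#' or rows x cols x 3 (RGB), intensities in `[0, 1]` — the layout returned
#' by the png/tiff/jpeg readers. An alpha channel, if present, is dropped.
#' PNG and TIFF round-trip losslessly; JPEG is lossy (shape and channel
#' count are preserved, values are not).
#'
#' @param path File path; `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` supported.
#' @return `read_image()` returns the image array; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '.%s' (use png/tiff/jpeg)", ext),
         call. = FALSE))
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1]
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @param img Image array with values in `[0, 1]`.
#' @export
write_image <- function(img, path) {
  if (any(img < 0 | img > 1)) stop("image values must lie in [0, 1]", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    jpg = ,
    jpeg = jpeg::writeJPEG(img, path, quality = 0.95),
    stop(sprintf("unsupported image format '.%s' (use png/tiff/jpeg)", ext),
         call. = FALSE))
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are stored as single-channel PNGs with values `{0, 255}` and read
#' back as strict 0/1 matrices; any gray introduced by foreign tooling is
#' rejected rather than silently thresholded.
#'
#' @param mask A 0/1 matrix.
#' @param path PNG path.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask)
  png::writePNG(as_storage_matrix(mask), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  v <- unique(as.vector(img))
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("mask file %s is not strictly binary {0,255}", path), call. = FALSE)
  }
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Convert an RGB image to unit-range grayscale
#'
#' Luma-weighted combination `0.299 R + 0.587 G + 0.114 B`. A single-channel
#' input is returned unchanged (already in `[0, 1]`).
#'
#' @param img rows x cols x 3 array (or matrix) with values in `[0, 1]`.
#' @return rows x cols matrix in `[0, 1]`.
#' @export
to_grayscale <- function(img) {
  if (length(dim(img)) == 2) return(img)
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("`img` must be grayscale or have exactly three channels", call. = FALSE)
  }
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
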