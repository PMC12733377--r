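# Internal helpers shared across modules.

# shape is always c(rows, cols); point coordinates are 0-based with
# x = column index and y = row index, pixel centers at integers.

img_shape <- function(img) {
  d <- dim(img)
  if (is.null(d)) stop("expected a matrix or array image", call. = FALSE)
  d[1:2]
}

n_channels <- function(img) {
  d <- dim(img)
  if (length(d) == 2) 1L else d[3]
}

check_binary <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("`%s` must be strictly binary (0/1)", arg), call. = FALSE)
  }
  invisible(mask)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("%s must have identical shape: %s vs %s", what,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")), call. = FALSE)
  }
  invisible(NULL)
}

# Evaluate `expr` under a private RNG stream derived from `seed`, restoring
# any pre-existing global RNG state afterwards. Keeps all randomness explicit.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Shift a matrix by (dr, dc) filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 3x3 square erosion with zero padding outside the frame, so that a
# full-frame mask erodes to its interior (unlike EBImage's replicate border).
erode3_zero <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out * shift_matrix(mask, dr, dc, fill = 0)
  }
  out
}

# Disc structuring element of a given width (odd); EBImage convention.
disc_brush <- function(size) {
  size <- as.integer(size)
  if (size < 1) stop("structuring element size must be positive", call. = FALSE)
  if (size %% 2 == 0) size <- size + 1L
  if (size == 1L) return(matrix(1, 1, 1))
  EBImage::makeBrush(size, shape = "disc")
}

as_storage_matrix <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m
}
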