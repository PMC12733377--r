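#' Phantom generation parameters
#'
#' Controls the synthetic paired-sample generator: a smooth random tissue
#' blob with speckled nuclear texture rendered twice — in an H&E-like
#' palette (light background, pink tissue, purple nuclei) for the fixed
#' frame and a fluorescence-like palette (dark background, green cytoplasm,
#' bright red nuclei) for the moving frame — related by a known degree-2
#' warp, with a tumor subregion whose outline is drawn on the annotated H&E
#' copy. Defaults emulate a modest whole-sample export: a 768 px frame with
#' tissue filling most of it, a tumor covering just under half the tissue, a
#' mild warp (quadratic coefficients up to 0.05 in normalized units, the
#' regime of FFPE-type deformation the registration is meant to absorb),
#' twelve boundary landmarks, and light sensor noise.
#'
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @param shape Fixed-frame `c(rows, cols)` (default `c(768, 768)`).
#' @param moving_shape Moving-frame shape (defaults to `shape`).
#' @param tissue_radius_frac Tissue blob radius as a fraction of the
#'   smaller image dimension (default 0.40).
#' @param boundary_amp Relative amplitude of the low-order radial
#'   perturbation shaping the blobs (default 0.025).
#' @param tumor_fraction Tumor radius as a fraction of the tissue radius
#'   (default 0.45).
#' @param nuclei_density Nuclear speckles per tissue pixel (default 0.004,
#'   mean spacing ~16 px).
#' @param warp Magnitude of the random degree-2 warp: quadratic terms drawn
#'   uniformly in `[-warp, warp]` (normalized coordinates), linear/constant
#'   deviations at half/quarter of that.
#' @param n_points Number of landmark pairs placed on the tissue boundary
#'   (>= 6; default 12).
#' @param jitter Gaussian displacement sigma (px) applied to the moving
#'   landmarks (default 0 = exact points).
#' @param tissue_loss Fraction of the moving-frame tissue area blanked out
#'   as loss patches (default 0), emulating tissue lost during FFPE
#'   processing.
#' @param loss_patches Number of loss patches (default 3).
#' @param noise Additive Gaussian intensity noise sigma (default 0.01).
#' @param stroke_thickness Annotation stroke width in px (default 3).
#' @param stroke_color RGB of the drawn outline (default green).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(seed, shape = c(768, 768), moving_shape = NULL,
                           tissue_radius_frac = 0.40, boundary_amp = 0.025,
                           tumor_fraction = 0.45, nuclei_density = 0.004,
                           warp = 0.05, n_points = 12, jitter = 0,
                           tissue_loss = 0, loss_patches = 3, noise = 0.01,
                           stroke_thickness = 3,
                           stroke_color = c(0.0, 0.65, 0.15)) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_points < 6) stop("`n_points` must be at least 6", call. = FALSE)
  fr <- c(tissue_radius_frac, tumor_fraction, tissue_loss)
  if (any(fr < 0) || any(fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (jitter < 0 || noise < 0 || warp < 0) {
    stop("`jitter`, `noise` and `warp` must be non-negative", call. = FALSE)
  }
  if (is.null(moving_shape)) moving_shape <- shape
  structure(list(seed = as.integer(seed), shape = as.integer(shape[1:2]),
                 moving_shape = as.integer(moving_shape[1:2]),
                 tissue_radius_frac = tissue_radius_frac,
                 boundary_amp = boundary_amp, tumor_fraction = tumor_fraction,
                 nuclei_density = nuclei_density, warp = warp,
                 n_points = as.integer(n_points), jitter = jitter,
                 tissue_loss = tissue_loss, loss_patches = as.integer(loss_patches),
                 noise = noise, stroke_thickness = as.integer(stroke_thickness),
                 stroke_color = stroke_color),
            class = "phantom_params")
}

# Star-shaped blob: radius R modulated by a low-order Fourier series.
blob_radius <- function(theta, R, amps) {
  r <- rep(R, length(theta))
  for (i in seq_along(amps$k)) {
    r <- r + R * (amps$a[i] * cos(amps$k[i] * theta) +
                  amps$b[i] * sin(amps$k[i] * theta))
  }
  r
}

blob_mask <- function(shape, center, R, amps) {
  dy <- matrix(0:(shape[1] - 1), shape[1], shape[2]) - center[2]
  dx <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE) - center[1]
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  matrix(as.numeric(rho <= blob_radius(theta, R, amps)), shape[1], shape[2])
}

draw_amps <- function(amp) {
  k <- 2:5
  list(k = k, a = stats::rnorm(length(k), sd = amp / sqrt(k)),
       b = stats::rnorm(length(k), sd = amp / sqrt(k)))
}

# Newton inversion of a degree-2 transform: find p with t(p) = q (pixels).
invert_transform_points <- function(t, q, tol = 1e-13, max_iter = 50) {
  stopifnot(inherits(t, "poly_transform"), t$normalization != "none")
  qn <- normalize_points(q, t$to_shape, t$normalization)
  pn <- qn
  a <- t$a; b <- t$b
  for (i in seq_len(max_iter)) {
    x <- pn[, 1]; y <- pn[, 2]
    fx <- a[1] + a[2] * x + a[3] * y + a[4] * x^2 + a[5] * x * y + a[6] * y^2 - qn[, 1]
    fy <- b[1] + b[2] * x + b[3] * y + b[4] * x^2 + b[5] * x * y + b[6] * y^2 - qn[, 2]
    if (max(abs(c(fx, fy))) < tol) break
    j11 <- a[2] + 2 * a[4] * x + a[5] * y
    j12 <- a[3] + a[5] * x + 2 * a[6] * y
    j21 <- b[2] + 2 * b[4] * x + b[5] * y
    j22 <- b[3] + b[5] * x + 2 * b[6] * y
    det <- j11 * j22 - j12 * j21
    if (any(abs(det) < 1e-12)) stop("transform is not invertible near the requested points", call. = FALSE)
    pn[, 1] <- x - (j22 * fx - j12 * fy) / det
    pn[, 2] <- y - (-j21 * fx + j11 * fy) / det
  }
  denormalize_points(pn, t$from_shape, t$normalization)
}

#' Generate a paired H&E/fluorescence phantom with known ground truth
#'
#' Produces a complete synthetic sample: the clean and annotated H&E-like
#' exports (differing only on the drawn tumor outline), the raw
#' fluorescence-like image obtained by pushing the fixed-frame fluorescence
#' scene through a known degree-2 warp, exact landmark pairs on the tissue
#' boundary (where human pickers find the strongest cross-modality
#' features), and every ground-truth object a test could need. The
#' ground-truth tumor mask is the region the drawn outline encloses
#' (stroke included). Deterministic for a given seed.
#'
#' @param params A [phantom_params()] object.
#' @return A list of class `phantom_sample` with elements `clean_he`,
#'   `annotated_he`, `raw_muse`, `true_tumor_mask_fixed`,
#'   `true_tumor_mask_raw`, `true_tissue_mask`, `true_tissue_mask_raw`,
#'   `true_transform` (moving to fixed), `control_points` and `params`.
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  with_local_seed(params$seed, generate_phantom_impl(params))
}

generate_phantom_impl <- function(p) {
  shape <- p$shape; mshape <- p$moving_shape
  R <- p$tissue_radius_frac * min(shape)
  center <- c((shape[2] - 1) / 2, (shape[1] - 1) / 2)  # (x, y)

  tissue_amps <- draw_amps(p$boundary_amp)
  tissue <- blob_mask(shape, center, R, tissue_amps)

  # tumor blob placed fully interior to the tissue
  # tumors may approach the tissue margin (that is what margin assessment is
  # about); only full containment in the tissue is enforced
  Rt <- p$tumor_fraction * R
  max_off <- max(0, R * (1 - 3 * p$boundary_amp) - Rt * (1 + 3 * p$boundary_amp) - 5)
  ang <- stats::runif(1, 0, 2 * pi)
  off <- stats::runif(1, 0, max_off)
  tcenter <- center + off * c(cos(ang), sin(ang))
  tumor_amps <- draw_amps(p$boundary_amp)
  tumor <- blob_mask(shape, tcenter, Rt, tumor_amps)
  tumor <- tumor * tissue  # safety; interior placement makes this a no-op

  # nuclear speckle shared between the palettes (same tissue, two stains)
  n_dots <- max(1L, round(p$nuclei_density * sum(tissue)))
  inside <- which(tissue == 1)
  dots <- matrix(0, shape[1], shape[2])
  dots[sample(inside, min(n_dots, length(inside)))] <- 1
  nuclei <- as_storage_matrix(EBImage::dilate(dots, disc_brush(3))) * tissue

  paint <- function(bg, tis, nuc) {
    img <- array(0, c(shape, 3))
    for (k in 1:3) {
      ch <- matrix(bg[k], shape[1], shape[2])
      ch[tissue == 1] <- tis[k]
      ch[nuclei == 1] <- nuc[k]
      img[, , k] <- ch
    }
    img
  }
  he <- paint(c(0.96, 0.95, 0.97), c(0.92, 0.60, 0.78), c(0.36, 0.20, 0.55))
  muse_scene <- paint(c(0.02, 0.02, 0.02), c(0.06, 0.35, 0.08), c(0.90, 0.25, 0.10))

  if (p$noise > 0) {
    he <- clamp01(he + array(stats::rnorm(length(he), sd = p$noise), dim(he)))
  }
  clean_he <- he

  # annotation stroke: ring of the tumor mask, outer edge on the mask boundary
  ring <- tumor
  er <- tumor
  for (i in seq_len(p$stroke_thickness)) er <- erode3_zero(er)
  ring <- tumor * (1 - er)
  annotated_he <- clean_he
  for (k in 1:3) {
    ch <- annotated_he[, , k]
    ch[ring == 1] <- p$stroke_color[k]
    annotated_he[, , k] <- ch
  }

  # known degree-2 warp, moving -> fixed, in normalized coordinates
  w <- p$warp
  rv <- function(m) if (m == 0) 0 else stats::runif(1, -m, m)
  a <- c(rv(w / 4), 1 + rv(w / 2), rv(w / 2), rv(w), rv(w), rv(w))
  b <- c(rv(w / 4), rv(w / 2), 1 + rv(w / 2), rv(w), rv(w), rv(w))
  # center the warp: the operator frames the sample, so the tissue center
  # maps to the frame center; only the differential deformation varies
  cm <- c(((mshape[2] - 1) / 2) / mshape[2], ((mshape[1] - 1) / 2) / mshape[1])
  cf <- c(center[1] / shape[2], center[2] / shape[1])
  bas <- c(1, cm[1], cm[2], cm[1]^2, cm[1] * cm[2], cm[2]^2)
  a[1] <- a[1] + (cf[1] - sum(a * bas))
  b[1] <- b[1] + (cf[2] - sum(b * bas))
  t_true <- poly_transform(a, b, direction = "moving_to_fixed",
                           normalization = "wh",
                           from_shape = mshape, to_shape = shape)

  # tissue must stay inside the moving frame under the inverse warp
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  bound_fixed <- cbind(center[1] + blob_radius(th, R, tissue_amps) * cos(th),
                       center[2] + blob_radius(th, R, tissue_amps) * sin(th))
  bound_moving <- invert_transform_points(t_true, bound_fixed)
  if (any(bound_moving[, 1] < 2) || any(bound_moving[, 1] > mshape[2] - 3) ||
      any(bound_moving[, 2] < 2) || any(bound_moving[, 2] > mshape[1] - 3)) {
    stop("warp too strong: tissue leaves the moving frame", call. = FALSE)
  }

  raw_muse <- warp_image(muse_scene, t_true, out_shape = mshape,
                         interpolation = "bilinear", fill = 0.02)
  tumor_raw <- warp_image(tumor, t_true, out_shape = mshape,
                          interpolation = "nearest")
  tissue_raw <- warp_image(tissue, t_true, out_shape = mshape,
                           interpolation = "nearest")

  if (p$tissue_loss > 0 && p$loss_patches > 0) {
    # FFPE losses tear pieces off the margin: bites centered on the tissue
    # boundary (interior holes would be undone by the hole-filling step
    # anyway); roughly half of each bite disc lies outside the tissue
    lost_area <- p$tissue_loss * sum(tissue_raw)
    pr <- sqrt(2 * lost_area / (p$loss_patches * pi))
    rim <- tissue_raw - erode3_zero(tissue_raw)
    rim_px <- which(rim == 1, arr.ind = TRUE)
    idx <- rim_px[sample(nrow(rim_px), p$loss_patches), , drop = FALSE]
    loss_centers <- cbind(idx[, 2] - 1, idx[, 1] - 1)
    for (i in seq_len(p$loss_patches)) {
      patch <- disc_at(mshape, loss_centers[i, ], pr)
      for (k in 1:3) {
        ch <- raw_muse[, , k]
        ch[patch == 1] <- 0.02
        raw_muse[, , k] <- ch
      }
    }
    loss_radius <- pr
  } else {
    loss_centers <- NULL
    loss_radius <- 0
  }
  if (p$noise > 0) {
    raw_muse <- clamp01(raw_muse +
      array(stats::rnorm(length(raw_muse), sd = p$noise), dim(raw_muse)))
  }

  # exact landmark pairs on the tissue boundary
  phase <- stats::runif(1, 0, 2 * pi)
  ang_k <- phase + seq(0, 2 * pi, length.out = p$n_points + 1)[-(p$n_points + 1)]
  fixed_pts <- cbind(center[1] + blob_radius(ang_k, R, tissue_amps) * cos(ang_k),
                     center[2] + blob_radius(ang_k, R, tissue_amps) * sin(ang_k))
  moving_pts <- invert_transform_points(t_true, fixed_pts)
  # where tissue was lost, the boundary the human picker relies on is gone:
  # landmarks inside a loss bite snap to the bite rim, corrupting the
  # registration exactly the way severe FFPE loss does
  if (!is.null(loss_centers)) {
    for (i in seq_len(nrow(loss_centers))) {
      dv <- sweep(moving_pts, 2, loss_centers[i, ])
      dist <- sqrt(rowSums(dv^2))
      hit <- dist < loss_radius & dist > 0
      if (any(hit)) {
        moving_pts[hit, ] <- loss_centers[rep(i, sum(hit)), , drop = FALSE] +
          dv[hit, , drop = FALSE] * (loss_radius / dist[hit])
      }
    }
  }
  cp <- control_points(data.frame(fixed_x = fixed_pts[, 1], fixed_y = fixed_pts[, 2],
                                  moving_x = moving_pts[, 1], moving_y = moving_pts[, 2]),
                       fixed_shape = shape, moving_shape = mshape)
  if (p$jitter > 0) {
    cp <- perturb_control_points(cp, p$jitter,
                                 seed = (p$seed * 7 + 1) %% .Machine$integer.max)
  }

  structure(list(clean_he = clean_he, annotated_he = annotated_he,
                 raw_muse = raw_muse, true_tumor_mask_fixed = tumor,
                 true_tumor_mask_raw = tumor_raw, true_tissue_mask = tissue,
                 true_tissue_mask_raw = tissue_raw, true_transform = t_true,
                 control_points = cp, params = p),
            class = "phantom_sample")
}

disc_at <- function(shape, center, radius) {
  dy <- matrix(0:(shape[1] - 1), shape[1], shape[2]) - center[2]
  dx <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE) - center[1]
  matrix(as.numeric(dx^2 + dy^2 <= radius^2), shape[1], shape[2])
}

#' Write a phantom sample to disk
#'
#' Persists the full sample in the interchange formats the pipeline
#' consumes: PNG images and masks, a CSV of control points and a JSON of
#' the true transform.
#'
#' @param sample A [generate_phantom()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_phantom <- function(sample, out_dir) {
  stopifnot(inherits(sample, "phantom_sample"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_image(sample$clean_he, file.path(out_dir, "clean_he.png"))
  write_image(sample$annotated_he, file.path(out_dir, "annotated_he.png"))
  write_image(sample$raw_muse, file.path(out_dir, "raw_muse.png"))
  write_mask(sample$true_tumor_mask_fixed, file.path(out_dir, "true_tumor_mask_fixed.png"))
  write_mask(sample$true_tumor_mask_raw, file.path(out_dir, "true_tumor_mask_raw.png"))
  write_mask(sample$true_tissue_mask, file.path(out_dir, "true_tissue_mask.png"))
  write_points(sample$control_points, file.path(out_dir, "control_points.csv"))
  write_transform(sample$true_transform, file.path(out_dir, "true_transform.json"))
  invisible(out_dir)
}
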