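#' Refine the annotation against the tissue mask
#'
#' The drawn annotation may include background the pathologist kept on
#' purpose (possible tumor in deeper sections) that has no counterpart in a
#' surface fluorescence image. The refined annotation is the overlap of the
#' annotation mask with the tissue mask after eroding the latter with a disc
#' element, which also trims boundary artifacts of the tissue segmentation.
#'
#' @param annotation_mask,tissue_mask 0/1 matrices of equal shape.
#' @param erosion_size Disc width of the tissue-mask erosion (px, default 15).
#' @return 0/1 mask; always a subset of both inputs. Warns when the overlap
#'   is empty (annotation entirely over background).
#' @export
refine_annotation <- function(annotation_mask, tissue_mask, erosion_size = 15) {
  check_binary(annotation_mask, "annotation_mask")
  check_binary(tissue_mask, "tissue_mask")
  check_same_shape(annotation_mask, tissue_mask, "masks")
  eroded <- if (sum(tissue_mask) == 0) tissue_mask else
    as_storage_matrix(EBImage::erode(tissue_mask, disc_brush(erosion_size)))
  refined <- annotation_mask * eroded
  if (sum(refined) == 0) {
    warning("refined annotation is empty: the annotation does not overlap the (eroded) tissue mask")
  }
  refined
}

#' Boundary of a binary region
#'
#' The outline is the mask minus its one-pixel erosion (3x3 square element,
#' zero-padded at the frame), i.e. every foreground pixel with a background
#' or out-of-frame neighbor: 8-connected foreground against 4-connected
#' background. A full-frame mask yields the border ring; a single pixel is
#' its own boundary.
#'
#' @param mask 0/1 matrix.
#' @return A tibble of class `outline` with 0-based `x`, `y` pixel columns
#'   and a `shape` attribute.
#' @export
boundary_of <- function(mask) {
  check_binary(mask)
  b <- mask - erode3_zero(mask)
  idx <- which(b == 1, arr.ind = TRUE)
  out <- tibble::tibble(x = as.numeric(idx[, 2] - 1), y = as.numeric(idx[, 1] - 1))
  structure(out, shape = dim(mask), class = c("outline", class(out)))
}

outline_shape <- function(o) attr(o, "shape")

#' Carry a refined H&E-space mask back to raw fluorescence space
#'
#' Fits the role-swapped (fixed-to-moving) transform from the same landmark
#' pairs and warps the mask with nearest-neighbor sampling, which keeps it
#' strictly binary.
#'
#' @param refined_mask 0/1 mask in the fixed (H&E-aligned) frame.
#' @param points [control_points()] used for the registration.
#' @param raw_shape `c(rows, cols)` of the raw fluorescence image.
#' @param normalization,condition_cap Passed to [fit_transform()].
#' @return 0/1 mask in raw fluorescence pixel space.
#' @export
inverse_transfer <- function(refined_mask, points, raw_shape = NULL,
                             normalization = "wh", condition_cap = 1e8) {
  check_binary(refined_mask, "refined_mask")
  t_inv <- fit_transform(points, direction = "moving_to_fixed",
                         normalization = normalization,
                         condition_cap = condition_cap)
  if (is.null(raw_shape)) raw_shape <- attr(points, "moving_shape")
  warp_image(refined_mask, t_inv, out_shape = raw_shape,
             interpolation = "nearest", fill = 0)
}

#' Draw an outline onto an image
#'
#' Renders the outline, dilated to the requested stroke thickness, in the
#' given color over a copy of the image; every other pixel is untouched.
#' Out-of-bounds outline points are clipped with a warning.
#'
#' @param img Image array (grayscale or RGB) in `[0, 1]`.
#' @param outline An [boundary_of()] result or two-column `(x, y)` table of
#'   0-based pixel coordinates.
#' @param color Length-3 RGB (or length-1 gray) vector in `[0, 1]`.
#' @param thickness Stroke width in pixels (disc dilation of the outline).
#' @return The annotated image.
#' @export
overlay_outline <- function(img, outline, color = c(0, 1, 0), thickness = 3) {
  shape <- img_shape(img)
  p <- as_xy_matrix(as.data.frame(outline)[, c("x", "y")])
  if (nrow(p) == 0) return(img)
  inb <- p[, 1] >= 0 & p[, 1] <= shape[2] - 1 & p[, 2] >= 0 & p[, 2] <= shape[1] - 1
  if (!all(inb)) {
    warning(sprintf("%d outline point(s) outside the image were clipped", sum(!inb)))
    p <- p[inb, , drop = FALSE]
    if (nrow(p) == 0) return(img)
  }
  stroke <- matrix(0, shape[1], shape[2])
  stroke[cbind(round(p[, 2]) + 1, round(p[, 1]) + 1)] <- 1
  if (thickness > 1) {
    stroke <- as_storage_matrix(EBImage::dilate(stroke, disc_brush(thickness)))
  }
  on <- stroke == 1
  if (n_channels(img) == 1) {
    img[on] <- color[1]
  } else {
    for (k in 1:3) {
      ch <- img[, , k]
      ch[on] <- color[min(k, length(color))]
      img[, , k] <- ch
    }
  }
  img
}

#' Run the full annotation-transfer pipeline
#'
#' End-to-end composition: fit the landmark registration, warp the raw
#' fluorescence image into the H&E frame, extract the drawn annotation from
#' the H&E export pair, compute the tissue mask on the registered image,
#' refine the annotation against the eroded tissue mask, inverse-register
#' the refined mask into raw fluorescence space, and render the final
#' annotated fluorescence image. Deterministic given inputs and
#' configuration; any stage failure aborts with a stage-labeled error.
#'
#' @param annotated_he,clean_he,raw_muse Image arrays or file paths.
#' @param points A [control_points()] object or a points file path.
#' @param config A [pipeline_config()].
#' @param registration_metric Also compute the tissue-overlap Dice between
#'   the registered fluorescence image and the fixed image (the score the
#'   interactive landmark-refinement loop watches). Costs a second
#'   tissue-mask computation; set `FALSE` in batch runs that do not need it.
#' @return A list of class `transfer_result` with elements `transform`
#'   (moving to fixed), `inverse_transform`, `registered_muse`,
#'   `annotation_mask`, `tissue_mask`, `refined_mask`, `transferred_mask`,
#'   `outline`, `overlay_image`, `registration_dice` and `provenance`.
#' @export
run_pipeline <- function(annotated_he, clean_he, raw_muse, points,
                         config = pipeline_config(), registration_metric = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  prov <- list(config = unclass(config), inputs = list())
  load_img <- function(x, name) {
    if (is.character(x)) {
      prov$inputs[[name]] <<- list(path = x, md5 = unname(tools::md5sum(x)))
      stage(name, read_image(x))
    } else {
      prov$inputs[[name]] <<- list(shape = dim(x), sum = sum(x))
      x
    }
  }
  annotated_he <- load_img(annotated_he, "read annotated H&E")
  clean_he <- load_img(clean_he, "read clean H&E")
  raw_muse <- load_img(raw_muse, "read raw fluorescence image")
  fixed_shape <- img_shape(annotated_he)
  moving_shape <- img_shape(raw_muse)
  if (is.character(points)) {
    points <- stage("read control points",
                    read_points(points, fixed_shape, moving_shape))
  }
  reg <- config$registration
  t_fwd <- stage("fit registration transform",
                 fit_transform(points, "moving_to_fixed",
                               normalization = reg$normalization,
                               condition_cap = reg$condition_cap))
  t_bwd <- stage("fit inverse transform",
                 fit_transform(points, "fixed_to_moving",
                               normalization = reg$normalization,
                               condition_cap = reg$condition_cap))
  registered <- stage("warp fluorescence image into H&E frame",
                      warp_image(raw_muse, t_bwd, out_shape = fixed_shape,
                                 interpolation = "bilinear"))
  ann <- stage("extract annotation mask",
               extract_annotation_mask(annotated_he, clean_he,
                                       diff_threshold = config$extraction$diff_threshold,
                                       closing_radius = config$extraction$closing_radius))
  tm <- stage("compute tissue mask", compute_tissue_mask(registered, config$tissue_mask))
  refined <- stage("refine annotation",
                   refine_annotation(ann, tm, config$transfer$erosion_size))
  transferred <- stage("inverse transfer",
                       warp_image(refined, t_fwd, out_shape = moving_shape,
                                  interpolation = "nearest"))
  outline <- stage("trace outline", boundary_of(transferred))
  overlay <- stage("render overlay",
                   overlay_outline(raw_muse, outline,
                                   color = config$transfer$overlay_color,
                                   thickness = config$transfer$overlay_thickness))
  reg_dice <- if (!registration_metric) NA_real_ else stage("registration quality", {
    fixed_tm <- tryCatch(compute_tissue_mask(clean_he, config$tissue_mask),
                         error = function(e) NULL)
    if (is.null(fixed_tm)) NA_real_ else registration_quality(tm, fixed_tm)
  })
  structure(list(transform = t_fwd, inverse_transform = t_bwd,
                 registered_muse = registered, annotation_mask = ann,
                 tissue_mask = tm, refined_mask = refined,
                 transferred_mask = transferred, outline = outline,
                 overlay_image = overlay, registration_dice = reg_dice,
                 provenance = prov),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("<transfer_result>\n")
  cat(sprintf("  fixed frame : %s\n", paste(dim(x$annotation_mask), collapse = "x")))
  cat(sprintf("  raw frame   : %s\n", paste(dim(x$transferred_mask), collapse = "x")))
  cat(sprintf("  annotation px: %d -> refined %d -> transferred %d\n",
              sum(x$annotation_mask), sum(x$refined_mask), sum(x$transferred_mask)))
  if (is.finite(x$registration_dice))
    cat(sprintf("  registration tissue Dice: %.3f\n", x$registration_dice))
  invisible(x)
}

#' Persist every artifact of a pipeline run
#'
#' @param result A `transfer_result`.
#' @param out_dir Output directory (created if missing).
#' @param save_intermediates Also write the registered image and the
#'   intermediate masks.
#' @return `out_dir`, invisibly.
#' @export
write_transfer_result <- function(result, out_dir, save_intermediates = FALSE) {
  stopifnot(inherits(result, "transfer_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_image(clamp01(result$overlay_image), file.path(out_dir, "overlay.png"))
  write_mask(result$transferred_mask, file.path(out_dir, "transferred_mask.png"))
  write_transform(result$transform, file.path(out_dir, "transform.json"))
  rep <- list(registration_dice = result$registration_dice,
              annotation_px = sum(result$annotation_mask),
              refined_px = sum(result$refined_mask),
              transferred_px = sum(result$transferred_mask),
              transform = glance(result$transform),
              provenance = result$provenance)
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (save_intermediates) {
    write_image(clamp01(result$registered_muse), file.path(out_dir, "registered_muse.png"))
    write_mask(result$annotation_mask, file.path(out_dir, "annotation_mask.png"))
    write_mask(result$tissue_mask, file.path(out_dir, "tissue_mask.png"))
    write_mask(result$refined_mask, file.path(out_dir, "refined_mask.png"))
  }
  invisible(out_dir)
}
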