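test_that("refinement is the intersection with the eroded tissue mask", {
  # 8x8 toy masks against an exhaustive per-pixel oracle (erosion width 1
  # leaves the tissue mask untouched)
  ann <- matrix(0, 8, 8); ann[2:5, 2:6] <- 1
  tis <- matrix(0, 8, 8); tis[4:8, 1:8] <- 1
  ref <- refine_annotation(ann, tis, erosion_size = 1)
  for (i in 1:8) for (j in 1:8) {
    expect_identical(ref[i, j], ann[i, j] * tis[i, j])
  }
  expect_true(all(ref <= ann) && all(ref <= tis))
})

test_that("refinement keeps deep annotations and drops background-only ones", {
  shape <- c(200, 200)
  tis <- disc_mask(shape, 100, 100, 80)
  deep <- disc_mask(shape, 100, 100, 40)   # 40 px from the tissue boundary
  expect_identical(refine_annotation(deep, tis, erosion_size = 15), deep)
  outside <- disc_mask(shape, 15, 15, 8)
  expect_warning(ref <- refine_annotation(outside, tis, erosion_size = 15),
                 "does not overlap")
  expect_equal(sum(ref), 0)
  expect_error(refine_annotation(deep, tis[1:100, ]), "identical shape")
})

test_that("boundaries enumerate exactly the rim pixels", {
  m <- matrix(0, 10, 10); m[4:6, 4:6] <- 1     # 3x3 solid square
  b <- boundary_of(m)
  expect_equal(nrow(b), 8)                     # all but the center
  expect_false(any(b$x == 4 & b$y == 4))       # center (0-based 4,4) excluded
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  bs <- boundary_of(single)
  expect_equal(unname(unlist(bs[1, c("x", "y")])), c(2, 2))
  full <- matrix(1, 6, 7)
  bf <- boundary_of(full)
  expect_equal(nrow(bf), 2 * 6 + 2 * 7 - 4)    # border ring
  expect_equal(nrow(boundary_of(matrix(0, 4, 4))), 0)
})

test_that("inverse transfer reproduces identity and integer-shift oracles", {
  mask <- disc_mask(c(64, 64), 30, 28, 12)
  cp <- identity_cp(shape = c(64, 64))
  expect_identical(inverse_transfer(mask, cp), mask)
  p <- base_pts(64, 64)
  dx <- 5; dy <- -8
  # moving = fixed + (dx, dy): the mask lands shifted in the raw frame
  cps <- control_points(data.frame(fixed_x = p$x, fixed_y = p$y,
                                   moving_x = p$x + dx, moving_y = p$y + dy),
                        fixed_shape = c(64, 64), moving_shape = c(64, 64))
  out <- inverse_transfer(mask, cps)
  oracle <- annotransfer:::shift_matrix(mask, dy, dx, fill = 0)
  expect_equal(out, oracle)
})

test_that("overlay touches exactly the stroke pixels", {
  img <- array(0.5, c(40, 40, 3))
  expect_identical(overlay_outline(img, tibble::tibble(x = numeric(0), y = numeric(0))),
                   img)
  one <- overlay_outline(img, tibble::tibble(x = 10, y = 20), thickness = 1)
  changed <- which(apply(abs(one - img), c(1, 2), sum) > 0)
  expect_equal(length(changed), 1)
  expect_equal(one[21, 11, ], c(0, 1, 0))
  # disc-dilated stroke matches the morphological oracle
  ring <- circle_outline_mask(c(40, 40), 20, 20, 10)
  ol <- boundary_of(ring)
  three <- overlay_outline(img, ol, thickness = 3)
  stroke_oracle <- EBImage::dilate(ring, annotransfer:::disc_brush(3))
  n_changed <- sum(apply(abs(three - img), c(1, 2), max) > 0)
  expect_equal(n_changed, sum(stroke_oracle))
  expect_warning(overlay_outline(img, tibble::tibble(x = 100, y = 5)), "clipped")
})

test_that("the pipeline is deterministic and its masks nest correctly", {
  ph <- small_phantom(6)
  r1 <- run_pipeline(ph$annotated_he, ph$clean_he, ph$raw_muse, ph$control_points,
                     registration_metric = FALSE)
  r2 <- run_pipeline(ph$annotated_he, ph$clean_he, ph$raw_muse, ph$control_points,
                     registration_metric = FALSE)
  expect_identical(r1$transferred_mask, r2$transferred_mask)
  expect_identical(r1$refined_mask, r2$refined_mask)
  expect_identical(r1$overlay_image, r2$overlay_image)
  # refined mask is contained in both parents
  expect_true(all(r1$refined_mask <= r1$annotation_mask))
  expect_true(all(r1$refined_mask <= r1$tissue_mask))
  expect_identical(dim(r1$transferred_mask), dim(ph$raw_muse)[1:2])
})

test_that("pipeline stage failures carry the stage label", {
  ph <- small_phantom(7)
  expect_error(run_pipeline("/nonexistent/annotated.png", ph$clean_he,
                            ph$raw_muse, ph$control_points),
               "\\[read annotated H&E\\]")
  bad_cp <- identity_cp(shape = c(10, 10))   # wrong frame for these images
  expect_error(run_pipeline(ph$annotated_he, ph$clean_he, ph$raw_muse, bad_cp,
                            registration_metric = FALSE),
               "\\[")
})

test_that("pipeline artifacts persist and read back", {
  ph <- small_phantom(8)
  res <- run_pipeline(ph$annotated_he, ph$clean_he, ph$raw_muse,
                      ph$control_points, registration_metric = FALSE)
  dir <- withr::local_tempdir()
  write_transfer_result(res, dir, save_intermediates = TRUE)
  expect_true(file.exists(file.path(dir, "overlay.png")))
  back <- read_mask(file.path(dir, "transferred_mask.png"))
  expect_identical(back, res$transferred_mask)
  t_back <- read_transform(file.path(dir, "transform.json"))
  expect_equal(t_back$a, res$transform$a)
  rep <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(rep$transferred_px, sum(res$transferred_mask))
})
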