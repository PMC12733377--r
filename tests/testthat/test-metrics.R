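# Brute-force oracles, independent of the implementation path.
dice_oracle <- function(m1, m2) {
  inter <- 0; s1 <- 0; s2 <- 0
  for (i in seq_len(nrow(m1))) for (j in seq_len(ncol(m1))) {
    s1 <- s1 + m1[i, j]; s2 <- s2 + m2[i, j]
    if (m1[i, j] == 1 && m2[i, j] == 1) inter <- inter + 1
  }
  if (s1 + s2 == 0) 1 else 2 * inter / (s1 + s2)
}

hausdorff_oracle <- function(p1, p2) {
  sup <- function(a, b) {
    worst <- 0
    for (i in seq_len(nrow(a))) {
      best <- Inf
      for (j in seq_len(nrow(b))) {
        best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
      }
      worst <- max(worst, best)
    }
    worst
  }
  max(sup(p1, p2), sup(p2, p1))
}

test_that("Dice reproduces the limiting cases and the direct formula", {
  m <- disc_mask(c(30, 30), 15, 15, 6)
  expect_equal(dice(m, m), 1.0)
  m2 <- disc_mask(c(30, 30), 5, 5, 3)
  expect_equal(dice(m, m2), 0.0)
  # |i1| = |i2| = 4, overlap 2 -> 0.5
  a <- matrix(0, 4, 4); a[1, 1:4] <- 1
  b <- matrix(0, 4, 4); b[1, 3:4] <- 1; b[2, 1:2] <- 1
  expect_equal(dice(a, b), 0.5)
  # degenerate conventions
  z <- matrix(0, 4, 4)
  expect_equal(dice(z, z), 1.0)
  expect_equal(dice(z, a), 0.0)
  expect_error(dice(a, matrix(0, 5, 4)), "identical shape")
  expect_error(dice(a * 0.5, a), "binary")
})

test_that("Dice equals the pixel-counting oracle on random masks", {
  for (seed in 1:50) {
    m1 <- random_mask(seed, 16)
    m2 <- random_mask(seed + 1000, 16)
    expect_equal(dice(m1, m2), dice_oracle(m1, m2), tolerance = 1e-12)
    expect_identical(dice(m1, m2), dice(m2, m1))   # symmetric
  }
})

test_that("Hausdorff distance matches hand and brute-force values", {
  o1 <- tibble::tibble(x = 0, y = 0)
  o2 <- tibble::tibble(x = 3, y = 4)
  expect_equal(hausdorff_distance(o1, o2, shape = c(100, 100)), 0.05)
  expect_equal(hausdorff_distance(o1, o1, shape = c(100, 100)), 0)
  for (seed in 1:30) {
    p1 <- annotransfer:::with_local_seed(seed,
      cbind(x = stats::runif(25, 0, 31), y = stats::runif(25, 0, 31)))
    p2 <- annotransfer:::with_local_seed(seed + 500,
      cbind(x = stats::runif(40, 0, 31), y = stats::runif(40, 0, 31)))
    got <- hausdorff_distance(as.data.frame(p1), as.data.frame(p2),
                              shape = c(32, 32), normalize = FALSE)
    expect_identical(got, hausdorff_oracle(p1, p2))
    # symmetry and the directed decomposition
    expect_identical(got, hausdorff_distance(as.data.frame(p2), as.data.frame(p1),
                                             shape = c(32, 32), normalize = FALSE))
    d12 <- hausdorff_distance(as.data.frame(p1), as.data.frame(p2),
                              shape = c(32, 32), normalize = FALSE, directed = "1to2")
    d21 <- hausdorff_distance(as.data.frame(p1), as.data.frame(p2),
                              shape = c(32, 32), normalize = FALSE, directed = "2to1")
    expect_identical(got, max(d12, d21))
  }
  expect_error(hausdorff_distance(o1[0, ], o2, shape = c(10, 10)), "empty outline")
})

test_that("metrics are invariant under a common rigid shift", {
  m1 <- disc_mask(c(60, 60), 20, 20, 8)
  m2 <- disc_mask(c(60, 60), 24, 21, 9)
  s1 <- annotransfer:::shift_matrix(m1, 10, 15)
  s2 <- annotransfer:::shift_matrix(m2, 10, 15)
  expect_equal(dice(m1, m2), dice(s1, s2))
  h1 <- hausdorff_distance(boundary_of(m1), boundary_of(m2), shape = c(60, 60))
  h2 <- hausdorff_distance(boundary_of(s1), boundary_of(s2), shape = c(60, 60))
  expect_equal(h1, h2)
})

test_that("feature similarity honors the extractor contract", {
  img <- small_phantom(2)$raw_muse
  expect_equal(feature_similarity(img, img), 1.0, tolerance = 1e-12)
  # orthogonal handcrafted extractor
  ortho <- function(im) if (mean(im) > 0.5) c(1, 0) else c(0, 1)
  bright <- array(0.9, c(8, 8, 3)); dark <- array(0.1, c(8, 8, 3))
  expect_equal(feature_similarity(bright, dark, ortho), 0)
  # cosine recomputed independently from the extractor's raw vectors
  ex <- extractor_builtin()
  other <- small_phantom(3)$raw_muse
  v1 <- ex(img); v2 <- ex(other)
  oracle <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  expect_equal(feature_similarity(img, other, ex), oracle, tolerance = 1e-12)
  expect_error(feature_similarity(img, img, function(im) c(0, 0)), "zero-norm")
})

test_that("single-sample evaluation reports all three metrics coherently", {
  ph <- small_phantom(4)
  m <- ph$true_tumor_mask_raw
  rep1 <- evaluate_transfer(m, m, ph$raw_muse, ph$raw_muse, sample_id = "self")
  expect_equal(rep1$dsc, 1.0)
  expect_equal(rep1$hausdorff_normalized, 0.0)
  expect_equal(rep1$feature_similarity, 1.0, tolerance = 1e-12)
  expect_false(rep1$empty_mask)
  # masks only: feature term stays NA
  rep2 <- evaluate_transfer(m, ph$true_tissue_mask_raw)
  expect_true(is.na(rep2$feature_similarity))
  expect_lt(rep2$dsc, 1)
})

test_that("batch summaries match a sort-based order-statistics oracle", {
  v <- 1:100
  reports <- tibble::tibble(dsc = as.numeric(v),
                            feature_similarity = NA_real_,
                            hausdorff_normalized = NA_real_)
  s <- summarize_batch(reports)
  row <- s[s$metric == "dsc", ]
  expect_equal(row$median, 50.5)
  expect_equal(row$q25, 25.75)
  expect_equal(row$q75, 75.25)
  expect_equal(row$min, 1); expect_equal(row$max, 100)
  expect_equal(row$outliers[[1]], numeric(0))
  # single report: all statistics collapse onto the value
  one <- summarize_batch(tibble::tibble(dsc = 0.9, feature_similarity = 0.95,
                                        hausdorff_normalized = 0.1))
  expect_true(all(one$min == one$max & one$min == one$median))
  # constant batch: IQR 0, no outliers
  const <- summarize_batch(tibble::tibble(dsc = rep(0.8, 7),
                                          feature_similarity = rep(0.9, 7),
                                          hausdorff_normalized = rep(0.2, 7)))
  expect_equal(const$q25, const$q75)
  expect_true(all(lengths(const$outliers) == 0))
  # 1.5 IQR whisker rule flags a far point
  vv <- c(0.85, 0.9, 0.88, 0.91, 0.89, 0.2)
  s2 <- summarize_batch(tibble::tibble(dsc = vv, feature_similarity = NA_real_,
                                       hausdorff_normalized = NA_real_))
  expect_equal(s2$outliers[s2$metric == "dsc"][[1]], 0.2)
  expect_error(summarize_batch(tibble::tibble(dsc = numeric(0),
                                              feature_similarity = numeric(0),
                                              hausdorff_normalized = numeric(0))),
               "empty batch")
})
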