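test_that("coordinate normalization divides by width/height and round-trips", {
  p <- normalize_points(cbind(37, 12), shape = c(100, 200))
  expect_equal(unname(p), cbind(37 / 200, 12 / 100))
  back <- denormalize_points(p, shape = c(100, 200))
  expect_equal(unname(back), cbind(37, 12))
  # origin and corner are fixed points of the convention
  expect_equal(unname(normalize_points(cbind(0, 0), c(55, 77))), cbind(0, 0))
  expect_equal(unname(normalize_points(cbind(77, 55), c(55, 77))), cbind(1, 1))
  expect_error(normalize_points(cbind(1, 1), c(0, 10)), "positive")
})

test_that("polynomial evaluation follows the degree-2 model exactly", {
  ident <- poly_transform(c(0, 1, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0),
                          normalization = "none")
  expect_equal(unname(evaluate_transform(ident, cbind(0.3, 0.7))),
               cbind(0.3, 0.7))
  a <- c(0.1681, 0.9862, 0.1141, 0.0281, -0.0755, -0.1059)
  b <- c(0.1227, -0.0214, 0.9980, 0.0635, -0.1174, 0.0190)
  t3 <- poly_transform(a, b, normalization = "none")
  # constant terms at the origin; full coefficient sums at (1, 1)
  expect_identical(unname(evaluate_transform(t3, cbind(0, 0))),
                   cbind(a[1], b[1]))
  expect_equal(unname(evaluate_transform(t3, cbind(1, 1))),
               cbind(sum(a), sum(b)))
  # generic point against an elementwise oracle
  x <- 0.4; y <- 0.25
  oracle <- c(sum(a * c(1, x, y, x^2, x * y, y^2)),
              sum(b * c(1, x, y, x^2, x * y, y^2)))
  expect_equal(as.vector(evaluate_transform(t3, cbind(x, y))), oracle)
  expect_error(evaluate_transform(t3, cbind(NaN, 0)), "finite")
})

test_that("fitting identity and translation point sets gives the closed-form coefficients", {
  cp <- identity_cp()
  t <- fit_transform(cp)
  expect_equal(t$a, c(0, 1, 0, 0, 0, 0), tolerance = 1e-10)
  expect_equal(t$b, c(0, 0, 1, 0, 0, 0), tolerance = 1e-10)

  # pure translation by (0.1, 0.2) in normalized units = (10, 20) px here
  p <- base_pts(); extra <- data.frame(x = c(10, 90), y = c(20, 35))
  p <- rbind(p, extra)
  cp2 <- control_points(data.frame(fixed_x = p$x + 10, fixed_y = p$y + 20,
                                   moving_x = p$x, moving_y = p$y),
                        fixed_shape = c(100, 100), moving_shape = c(100, 100))
  t2 <- fit_transform(cp2)
  expect_equal(t2$a, c(0.1, 1, 0, 0, 0, 0), tolerance = 1e-10)
  expect_equal(t2$b, c(0.2, 0, 1, 0, 0, 0), tolerance = 1e-10)
  # inverse fit negates the translation
  t2i <- fit_inverse_transform(cp2)
  expect_equal(t2i$a, c(-0.1, 1, 0, 0, 0, 0), tolerance = 1e-10)
  expect_equal(t2i$b, c(-0.2, 0, 1, 0, 0, 0), tolerance = 1e-10)
})

test_that("fitting recovers generating coefficients and interpolates with six pairs", {
  for (seed in 1:10) {
    gen <- random_mild_transform(seed)
    for (n in c(6, 12)) {
      cp <- cp_from_transform(gen, n = n, seed = seed + 100)
      fit <- fit_transform(cp)
      expect_lt(max(abs(c(fit$a - gen$a, fit$b - gen$b))), 1e-8)
      if (n == 6) expect_lt(max(attr(fit, "residuals")), 1e-9)
    }
  }
})

test_that("adding a point on the fitted surface leaves coefficients unchanged", {
  gen <- random_mild_transform(3)
  cp <- cp_from_transform(gen, n = 10, seed = 7)
  fit <- fit_transform(cp)
  extra_m <- cbind(41.5, 58.25)
  extra_f <- evaluate_transform(gen, extra_m)
  df <- rbind(as.data.frame(cp),
              data.frame(fixed_x = extra_f[1], fixed_y = extra_f[2],
                         moving_x = extra_m[1], moving_y = extra_m[2]))
  fit2 <- fit_transform(control_points(df, c(100, 100), c(100, 100)))
  expect_lt(max(abs(c(fit2$a - fit$a, fit2$b - fit$b))), 1e-8)
})

test_that("degenerate landmark sets are rejected with diagnostics", {
  # fewer than six distinct pairs (two duplicates collapse)
  df <- data.frame(fixed_x = c(0, 1, 2, 3, 4, 4), fixed_y = c(0, 1, 2, 3, 4, 4),
                   moving_x = c(0, 1, 2, 3, 4, 4), moving_y = c(0, 1, 2, 3, 4, 4))
  expect_error(control_points(df, c(10, 10), c(10, 10)), "at least six")
  # collinear points: quadratic design is rank deficient
  col <- data.frame(fixed_x = 0:5 * 10, fixed_y = 0:5 * 10,
                    moving_x = 0:5 * 10, moving_y = 0:5 * 10)
  cpc <- control_points(col, c(100, 100), c(100, 100))
  expect_error(fit_transform(cpc), "condition")
})

test_that("forward then role-swapped fits compose to near identity for mild warps", {
  # a degree-2 warp has no degree-2 inverse, so the composition error grows
  # with the quadratic magnitude: at the default mild level (0.05) it stays
  # below half a pixel per draw; at 0.1 that holds in the median
  shape <- c(1000, 1000)
  comp_rms <- function(seed, mag) {
    gen <- random_mild_transform(seed, shape = shape, mag = mag)
    cp <- cp_from_transform(gen, n = 12, shape = shape, seed = seed + 50)
    fwd <- fit_transform(cp, "moving_to_fixed")
    bwd <- fit_transform(cp, "fixed_to_moving")
    mv <- cbind(cp$moving_x, cp$moving_y)
    back <- evaluate_transform(bwd, evaluate_transform(fwd, mv))
    sqrt(mean(rowSums((back - mv)^2)))
  }
  expect_true(all(vapply(1:8, comp_rms, numeric(1), mag = 0.05) < 0.5))
  expect_lt(median(vapply(1:8, comp_rms, numeric(1), mag = 0.1)), 0.5)
})

test_that("refitting under the max-dimension normalization warps points identically", {
  gen <- random_mild_transform(11, shape = c(80, 120))
  cp <- cp_from_transform(gen, n = 10, shape = c(80, 120), seed = 5)
  f_wh <- fit_transform(cp, normalization = "wh")
  f_mx <- fit_transform(cp, normalization = "max")
  probe <- cbind(c(10, 55, 100, 33.5), c(12, 70, 40, 61.25))
  expect_equal(evaluate_transform(f_wh, probe), evaluate_transform(f_mx, probe),
               tolerance = 1e-8)
})

test_that("transform JSON serialization round-trips", {
  gen <- random_mild_transform(2)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(gen, path)
  back <- read_transform(path)
  expect_identical(back$a, gen$a)
  expect_identical(back$b, gen$b)
  expect_identical(back$direction, gen$direction)
  expect_identical(back$normalization, gen$normalization)
  expect_identical(back$from_shape, gen$from_shape)
})

test_that("tidy and glance expose the twelve coefficients and fit diagnostics", {
  cp <- identity_cp(n_extra = 4)
  fit <- fit_transform(cp)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 12)
  expect_equal(td$estimate[td$axis == "x"], fit$a)
  gl <- generics::glance(fit)
  expect_equal(gl$n_pairs, 10)
  expect_lt(gl$rms_px, 1e-9)
})
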