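test_that("Box-Cox transform hits its closed-form anchor points", {
  expect_equal(bc_transform(4, 0.5), 2.0)
  expect_equal(bc_transform(1, 0.7), 0.0)
  expect_equal(bc_transform(1, 0), 0.0)
  expect_equal(bc_transform(exp(1), 0), 1.0)
  expect_error(bc_transform(c(2, 0, 3), 0.5), "positive")
  expect_error(bc_transform(-1, 0), "positive")
})

test_that("transform and inverse round-trip and are continuous at lambda = 0", {
  xs <- c(1e-3, 0.1, 1, 2.5, 10, 500, 1e4)
  for (lam in c(0, 0.1, 0.25, 0.5, 1)) {
    expect_equal(as.numeric(bc_inverse(bc_transform(xs, lam), lam)), xs,
                 tolerance = 1e-9)
  }
  expect_lt(max(abs(bc_transform(xs, 1e-8) - log(xs))), 1e-6)
})

test_that("inverse transform clips impossible arguments to zero intake", {
  y <- bc_inverse(c(2, -10, 0), 0.5)
  expect_equal(as.numeric(y), c(4, 0, 1))
  expect_equal(attr(y, "n_clipped"), 1L)
  expect_equal(as.numeric(bc_inverse(0, 0.3)), 1)
})

test_that("default lambda grid spans 0..1 in 101 steps and contains the log case", {
  g <- lambda_grid()
  expect_length(g, 101)
  expect_true(0 %in% as.numeric(g))
  expect_error(lambda_grid(step = 0), "step")
  expect_error(lambda_grid(lo = -0.2), ">= 0")
})

test_that("probability-plot R2 separates normal from skewed residuals", {
  set.seed(401)
  z <- rnorm(10000)
  w <- rep(1, length(z))
  r2_norm <- normal_plot_r2(z, w)
  r2_skew <- normal_plot_r2(exp(z), w)
  expect_gt(r2_norm, 0.999)
  expect_lt(r2_skew, r2_norm)
  expect_error(normal_plot_r2(rep(1, 200)), "zero spread")
  expect_warning(normal_plot_r2(rnorm(50)), "fewer than 100")
})

test_that("weighted quantiles reduce to type 7 under equal weights", {
  x <- c(9, 1, 5, 3, 7)
  p <- c(0, 0.25, 0.5, 0.9, 1)
  expect_equal(weighted_quantile(x, rep(1, 5), p),
               unname(quantile(x, p, type = 7)))
  # replicating a point with split weight changes nothing
  expect_equal(weighted_quantile(c(x, 5), c(1, 1, 0.5, 1, 1, 0.5), p),
               weighted_quantile(x, rep(1, 5), p))
})

test_that("lambda selection recovers the generating transform", {
  g <- generate_recalls(generator_spec(n_persons = 5000, days_per_person = 1,
                                       beta_age = 0, beta_group = c(0, 0, 0),
                                       beta_weekend = 0, seed = 42))
  sel <- select_lambda(intake ~ 1, g$recalls, weights = "weight")
  expect_s3_class(sel, "lambda_selection")
  expect_equal(nrow(sel$profile), 101L)
  expect_lt(abs(sel$lambda - 0.25), 0.05)
  expect_equal(sel$r_squared, max(sel$profile$r2, na.rm = TRUE))

  # log-normal intakes select the log end of the grid
  g0 <- generate_recalls(generator_spec(n_persons = 5000, days_per_person = 1,
                                        lambda = 0, beta0 = 6, beta_age = 0,
                                        beta_group = c(0, 0, 0),
                                        beta_weekend = 0, seed = 43))
  sel0 <- select_lambda(intake ~ 1, g0$recalls, weights = "weight")
  expect_lte(sel0$lambda, 0.05)
})

test_that("lambda selection is invariant to rescaling the survey weights", {
  g <- tiny_recalls(n = 600, seed = 8)
  d <- g$recalls
  s1 <- select_lambda(full_formula, d, weights = d$weight)
  s2 <- select_lambda(full_formula, d, weights = d$weight * 7.3)
  expect_identical(s1$lambda, s2$lambda)
  expect_equal(s1$profile$r2, s2$profile$r2, tolerance = 1e-12)
})
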