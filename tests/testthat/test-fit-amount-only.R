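test_that("weighted ML matches the lme4 oracle at fixed lambda (equal weights)", {
  skip_if_not_installed("lme4")
  g <- tiny_recalls(n = 400, days = 2, seed = 9, weight_scheme = "equal")
  d <- g$recalls
  f <- fit_amount_only(full_formula, d, temporal = "weekend", lambda = 0.25)
  d$z <- bc_transform(d$intake, 0.25)
  m <- lme4::lmer(z ~ age + group + weekend + (1 | person_id), d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$sigma2_u, vc$vcov[1], tolerance = 1e-5)
  expect_equal(f$sigma2_e, vc$vcov[2], tolerance = 1e-5)
  expect_equal(unname(coef(f)), unname(lme4::fixef(m)), tolerance = 1e-6)
  # profile log-likelihood agrees too, up to the Box-Cox Jacobian term
  expect_equal(f$loglik - (0.25 - 1) * sum(log(d$intake)),
               as.numeric(logLik(m)), tolerance = 1e-6)
})

test_that("a single fixed seed recovers the generating parameters", {
  g <- generate_recalls(generator_spec(n_persons = 2000, days_per_person = 2,
                                       seed = 1))
  f <- fit_amount_only(full_formula, g$recalls, temporal = "weekend")
  # lambda is weakly identified at this scale (sampling SD ~ 0.05, the
  # same flatness that lets the two methods pick visibly different
  # transformations on real data), so a single draw is held to a 3-sigma
  # band; the ratio is tighter
  expect_lt(abs(f$lambda - 0.25), 0.15)
  expect_lt(abs(f$alpha / 2 - 1), 0.15)
  r <- extract_ratio(f)
  expect_s3_class(r, "variance_ratio")
  expect_equal(r$value, f$sigma2_e / f$sigma2_u)
})

test_that("the returned lambda maximises the stored profile likelihood", {
  g <- tiny_recalls(n = 300, days = 2, seed = 12)
  f <- fit_amount_only(full_formula, g$recalls, temporal = "weekend",
                       grid = lambda_grid(step = 0.1))
  expect_equal(nrow(f$lambda_profile), 11L)
  expect_equal(f$loglik, max(f$lambda_profile$loglik))
  expect_equal(f$lambda,
               f$lambda_profile$lambda[which.max(f$lambda_profile$loglik)])
})

test_that("ML within-person variance agrees with the paired-difference moment estimator", {
  g <- generate_recalls(generator_spec(n_persons = 3000, days_per_person = 2,
                                       seed = 15))
  d <- g$recalls
  f <- fit_amount_only(full_formula, d, temporal = "weekend")
  z <- bc_transform(d$intake, f$lambda)
  X <- model.matrix(full_formula, d)
  res <- z - drop(X %*% coef(f))
  dd <- res[d$day == 2] - res[d$day == 1]
  w1 <- d$weight[d$day == 1]
  moment <- 0.5 * sum(w1 * dd^2) / sum(w1)
  expect_lt(abs(f$sigma2_e / moment - 1), 0.05)
})

test_that("degenerate replicate structures hit the right boundaries", {
  g <- tiny_recalls(n = 200, days = 2, seed = 30)
  d <- g$recalls
  # identical recalls per person: all variation is between persons
  d0 <- d
  d0$intake <- rep(d0$intake[d0$day == 1], each = 2)
  f0 <- suppressWarnings(fit_amount_only(intake ~ age + group, d0,
                                         lambda = 0.25))
  expect_lt(f0$sigma2_e, 1e-6 * f0$sigma2_u)
  # identical person means, only days differ: no between-person variation
  n <- 100
  d1 <- data.frame(person_id = rep(1:n, each = 2), day = rep(1:2, n),
                   intake = rep(c(10, 20), n))
  expect_warning(f1 <- fit_amount_only(intake ~ 1, d1, lambda = 0.5),
                 "boundary 0")
  expect_identical(f1$alpha, Inf)
  expect_error(extract_ratio(f1), "boundary")
  # no replicate recalls at all
  expect_error(fit_amount_only(full_formula, d[d$day == 1, ],
                               temporal = "weekend"),
               "cannot separate variance components")
})

test_that("fitted ratio matches hand-computed component ratios", {
  # components like published amount-only fits: within 10.450 / between
  # 5.220 gives 2.002; within 3.262 / between 3.044 gives 1.072
  fake <- structure(list(sigma2_u = 5.220, sigma2_e = 10.450,
                         alpha = 10.450 / 5.220, boundary = FALSE),
                    class = c("amount_fit", "intake_fit"))
  expect_equal(round(extract_ratio(fake)$value, 3), 2.002)
  fake2 <- structure(list(sigma2_u = 3.044, sigma2_e = 3.262,
                          alpha = 3.262 / 3.044, boundary = FALSE),
                     class = c("amount_fit", "intake_fit"))
  expect_equal(round(extract_ratio(fake2)$value, 3), 1.072)
  expect_equal(extract_ratio(structure(list(sigma2_u = 1, sigma2_e = 1,
                                            alpha = 1, boundary = FALSE),
                                       class = c("amount_fit", "intake_fit")))$value,
               1)
})
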