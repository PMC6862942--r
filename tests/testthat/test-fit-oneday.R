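test_that("with lambda forced to 1 the intercept is the mean of intake - 1", {
  d <- data.frame(person_id = 1:200, day = 1,
                  intake = exp(rnorm(200, 2, 0.4)))
  f <- fit_oneday(intake ~ 1, d, ratio = variance_ratio(2, "within_between"),
                  lambda = 1)
  expect_equal(unname(coef(f)), mean(d$intake - 1))
  expect_equal(f$lambda, 1)
})

test_that("fit matches a weighted least-squares oracle at fixed lambda", {
  g <- tiny_recalls(n = 500, seed = 21)
  d <- g$recalls
  f <- fit_oneday(full_formula, d, ratio = variance_ratio(2, "within_between"),
                  temporal = "weekend", lambda = 0.25)
  d$z <- bc_transform(d$intake, 0.25)
  oracle <- lm(z ~ age + group + weekend, d, weights = weight)
  expect_equal(coef(f), coef(oracle), tolerance = 1e-10)
})

test_that("duplicating every record at half weight leaves the regression unchanged", {
  # coefficients are exactly weight-invariant; the total variance moves
  # only through the effective-degrees-of-freedom correction, which is
  # O(p / n_eff)
  g <- tiny_recalls(n = 300, seed = 5)
  d <- g$recalls
  d2 <- rbind(d, transform(d, person_id = person_id + max(person_id)))
  d2$weight <- d2$weight / 2
  f1 <- fit_oneday(full_formula, d, ratio = variance_ratio(2, "within_between"),
                   temporal = "weekend", lambda = 0.25)
  f2 <- fit_oneday(full_formula, d2, ratio = variance_ratio(2, "within_between"),
                   temporal = "weekend", lambda = 0.25)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(f1$V, f2$V, tolerance = 0.02)
  expect_equal(f1$sigma2_e / f1$sigma2_u, f2$sigma2_e / f2$sigma2_u,
               tolerance = 1e-12)
})

test_that("total variance splits exactly per the supplied external ratio", {
  g <- generate_recalls(generator_spec(n_persons = 5000, days_per_person = 1,
                                       lambda = 0.3, seed = 77))
  f <- fit_oneday(full_formula, g$recalls,
                  ratio = variance_ratio(2, "within_between"),
                  temporal = "weekend", lambda = 0.3)
  expect_equal(f$sigma2_e / f$sigma2_u, 2.0, tolerance = 1e-12)
  expect_equal(f$sigma2_u + f$sigma2_e, f$V, tolerance = 1e-9)
  # generator truth: sigma2_u + sigma2_e = 1.5 on this scale
  expect_lt(abs(f$V - 1.5) / 1.5, 0.1)
})

test_that("repeated recalls trigger the first-recall rule with a warning", {
  g <- tiny_recalls(n = 200, days = 2, seed = 3)
  expect_warning(
    f <- fit_oneday(full_formula, g$recalls,
                    ratio = variance_ratio(2, "within_between"),
                    temporal = "weekend", lambda = 0.25),
    "first recall")
  d1 <- g$recalls[g$recalls$day == 1, ]
  f1 <- fit_oneday(full_formula, d1,
                   ratio = variance_ratio(2, "within_between"),
                   temporal = "weekend", lambda = 0.25)
  expect_equal(coef(f), coef(f1))
})

test_that("degenerate designs fail loudly", {
  g <- tiny_recalls(n = 100, seed = 4)
  d <- g$recalls
  d$age2 <- 2 * d$age
  expect_error(fit_oneday(intake ~ age + age2, d,
                          ratio = variance_ratio(2, "within_between")),
               "collinear")
  expect_error(fit_oneday(full_formula, d[1:4, ],
                          ratio = variance_ratio(2, "within_between")),
               "at least")
})

test_that("zero intakes are shifted (or dropped) and counted", {
  g <- tiny_recalls(n = 300, seed = 6)
  d <- g$recalls
  d$intake[1:5] <- 0
  f <- fit_oneday(full_formula, d, ratio = variance_ratio(2, "within_between"),
                  lambda = 0.25)
  expect_equal(f$diagnostics$n_shifted, 5L)
  expect_equal(f$diagnostics$shift, min(d$intake[d$intake > 0]) / 2)
  fd <- fit_oneday(full_formula, d, ratio = variance_ratio(2, "within_between"),
                   lambda = 0.25, zero_handling = "drop")
  expect_equal(fd$diagnostics$n_dropped, 5L)
  expect_equal(fd$n, f$n - 5L)
  d$intake[1:30] <- 0
  expect_error(fit_oneday(full_formula, d,
                          ratio = variance_ratio(2, "within_between"),
                          lambda = 0.25),
               "nearly-daily")
})

test_that("linear predictors are stored at both day types for every person", {
  g <- tiny_recalls(n = 150, seed = 9)
  f <- fit_oneday(full_formula, g$recalls,
                  ratio = variance_ratio(2, "within_between"),
                  temporal = "weekend", lambda = 0.25)
  expect_equal(nrow(f$linpred), 150L)
  b_we <- coef(f)[["weekend"]]
  expect_equal(f$linpred$lp_weekend - f$linpred$lp_weekday,
               rep(b_we, 150), tolerance = 1e-12)
  # predict() averages the two day types
  avg <- predict(f)
  expect_equal(avg, 4 / 7 * f$linpred$lp_weekday + 3 / 7 * f$linpred$lp_weekend)
})
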