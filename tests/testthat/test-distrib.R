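test_that("per-person usual intake has closed forms at lambda 1 and 0", {
  # identity-like transform: within-person error integrates out exactly
  expect_equal(as.numeric(usual_intake_of_person(9, 9, 0, lambda = 1,
                                                 sigma2_e = 3.7)), 10)
  # log transform: lognormal mean exp(sigma^2 / 2)
  expect_equal(as.numeric(usual_intake_of_person(0, 0, 0, lambda = 0,
                                                 sigma2_e = 1)),
               exp(0.5), tolerance = 1e-6)
  expect_error(usual_intake_of_person(1, 1, 0, 0.5, 1, nodes = 4), "odd")
  expect_error(usual_intake_of_person(1, 1, 0, 0.5, 1, nodes = 1), "odd")
})

test_that("quadrature matches a brute-force Monte-Carlo expectation", {
  set.seed(99)
  e <- rnorm(1e6)
  for (lam in c(0.2, 0.4)) {
    for (s2 in c(0.3, 0.6)) {
      q <- as.numeric(usual_intake_of_person(3, 3, 0, lambda = lam,
                                             sigma2_e = s2, nodes = 9))
      mc <- mean(as.numeric(bc_inverse(3 + sqrt(s2) * e, lam)))
      expect_lt(abs(q / mc - 1), 0.005)
    }
  }
})

test_that("distribution estimation is deterministic given the seed", {
  g <- tiny_recalls(n = 200, seed = 2)
  f <- fit_oneday(full_formula, g$recalls,
                  ratio = variance_ratio(2, "within_between"),
                  temporal = "weekend", lambda = 0.25)
  e1 <- estimate_distribution(f, M = 30, seed = 11, cutoff = 500)
  e2 <- estimate_distribution(f, M = 30, seed = 11, cutoff = 500)
  expect_identical(summary(e1), summary(e2))
  e3 <- estimate_distribution(f, M = 30, seed = 12, cutoff = 500)
  expect_false(identical(e1$mean, e3$mean))
})

test_that("a symmetric fit centres the pseudo-population where expected", {
  # sigma2_e = 0, lambda = 1, all linear predictors 9: usual intakes are
  # N(10, sigma2_u), so the weighted median sits at 10 and half the mass
  # falls below it
  lp <- data.frame(person_id = 1:400, weight = 1,
                   lp_weekday = 9, lp_weekend = 9)
  f <- structure(list(method = "oneday", lambda = 1, sigma2_u = 1,
                      sigma2_e = 0, linpred = lp),
                 class = c("oneday_fit", "intake_fit"))
  est <- estimate_distribution(f, M = 100, seed = 4)
  expect_lt(abs(unname(est$percentiles["p50"]) - 10), 0.02)
  expect_lt(abs(prevalence_below(est, 10) - 0.5), 0.01)
  expect_lt(abs(est$mean - 10), 0.02)
})

test_that("prevalence below extreme cutoffs hits 0 and 1", {
  g <- tiny_recalls(n = 150, seed = 13)
  f <- fit_oneday(full_formula, g$recalls,
                  ratio = variance_ratio(2, "within_between"),
                  temporal = "weekend", lambda = 0.25)
  est <- estimate_distribution(f, M = 20, seed = 5)
  expect_equal(prevalence_below(est, min(est$pseudo$value) * 0.9), 0)
  expect_equal(prevalence_below(est, max(est$pseudo$value) * 1.1), 1)
  med <- unname(quantile(est, 0.5))
  expect_lt(abs(prevalence_below(est, med) - 0.5), 0.01)
  expect_error(prevalence_below(est, -1), "> 0")
})

test_that("percentiles are nondecreasing and M refines without shifting", {
  g <- tiny_recalls(n = 300, seed = 14)
  f <- fit_oneday(full_formula, g$recalls,
                  ratio = variance_ratio(2, "within_between"),
                  temporal = "weekend", lambda = 0.25)
  e50 <- estimate_distribution(f, M = 50, seed = 6)
  e500 <- estimate_distribution(f, M = 500, seed = 6)
  expect_true(all(diff(e50$percentiles) >= 0))
  # Monte-Carlo refinement: means agree well within the pseudo-population
  # spread scaled by the draw count
  se_mc <- sd(e50$pseudo$value) / sqrt(nrow(g$recalls) * 50)
  expect_lt(abs(e50$mean - e500$mean), 4 * se_mc + 1e-9)
})

test_that("estimating from a degenerate fit object fails cleanly", {
  lp <- data.frame(person_id = 1, weight = 1, lp_weekday = NA_real_,
                   lp_weekend = 1)
  bad <- structure(list(method = "oneday", lambda = 1, sigma2_u = -1,
                        sigma2_e = 0, linpred = lp),
                   class = c("oneday_fit", "intake_fit"))
  expect_error(estimate_distribution(bad), "nonnegative")
  bad$sigma2_u <- 1
  expect_error(estimate_distribution(bad), "missing linear predictors")
})
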