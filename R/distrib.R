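#' Day-type weights
#'
#' Mixing weights for averaging usual intake over day types. Defaults
#' follow the weekend definition Friday--Sunday: 4/7 weekday, 3/7
#' weekend.
#'
#' @param weekday,weekend nonnegative weights summing to 1.
#' @return named numeric vector.
#' @export
day_type_weights <- function(weekday = 4 / 7, weekend = 3 / 7) {
  if (weekday < 0 || weekend < 0 || abs(weekday + weekend - 1) > 1e-8) {
    stop_config("day-type weights must be nonnegative and sum to 1")
  }
  c(weekday = weekday, weekend = weekend)
}

#' Usual intake of a person given their random effect
#'
#' The usual intake of person \eqn{i} is the long-run average of their
#' daily intakes: on the transformed scale a day's intake is
#' \eqn{lp_t + u_i + e}, so the usual intake is
#' \deqn{T_i = \sum_t \pi_t \, E_e\left[ g^{-1}(lp_t + u_i + e;\,
#'   \lambda)\right], \quad e \sim N(0, \sigma^2_e),}
#' the within-person error integrated out for each day type \eqn{t} and
#' the day types mixed with weights \eqn{\pi_t}. The expectation is
#' evaluated by Gauss--Hermite quadrature (default 9 nodes). Negative
#' arguments of the inverse transform are clipped to zero intake; the
#' fraction of clipped node evaluations is attached as the
#' \code{"clipped_fraction"} attribute.
#'
#' All of \code{lp_weekday}, \code{lp_weekend}, \code{u} may be vectors
#' (recycled to a common length), so the whole pseudo-population is
#' evaluated in one call.
#'
#' @param lp_weekday,lp_weekend transformed-scale linear predictors.
#' @param u person-effect value(s) on the transformed scale.
#' @param lambda Box-Cox parameter of the fit.
#' @param sigma2_e within-person variance on the transformed scale.
#' @param daytype day-type mixing weights from [day_type_weights()].
#' @param nodes number of Gauss--Hermite nodes (odd, >= 3).
#' @return usual intake(s) in original units/day.
#' @examples
#' usual_intake_of_person(9, 9, 0, lambda = 1, sigma2_e = 5) # exactly 10
#' usual_intake_of_person(0, 0, 0, lambda = 0, sigma2_e = 1) # exp(1/2)
#' @export
usual_intake_of_person <- function(lp_weekday, lp_weekend, u,
                                   lambda, sigma2_e,
                                   daytype = day_type_weights(),
                                   nodes = 9) {
  if (nodes < 3 || nodes %% 2 == 0) {
    stop_config("quadrature nodes must be an odd number >= 3")
  }
  if (sigma2_e < 0) stop_model("sigma2_e must be nonnegative")
  n <- max(length(lp_weekday), length(lp_weekend), length(u))
  lp_wd <- rep_len(lp_weekday, n) + rep_len(u, n)
  lp_we <- rep_len(lp_weekend, n) + rep_len(u, n)

  gh <- pracma::gaussHermite(nodes)
  shift <- sqrt(2 * sigma2_e) * gh$x
  wq <- gh$w / sqrt(pi)

  acc <- numeric(n)
  n_clip <- 0
  for (k in seq_len(nodes)) {
    vwd <- bc_inverse(lp_wd + shift[k], lambda)
    vwe <- bc_inverse(lp_we + shift[k], lambda)
    n_clip <- n_clip + attr(vwd, "n_clipped") + attr(vwe, "n_clipped")
    acc <- acc + wq[k] *
      (daytype[["weekday"]] * as.numeric(vwd) +
       daytype[["weekend"]] * as.numeric(vwe))
  }
  attr(acc, "clipped_fraction") <- n_clip / (2 * n * nodes)
  acc
}

#' Estimate the population distribution of usual intake
#'
#' Converts a fitted model (either [fit_oneday()] or [fit_amount_only()])
#' into the population usual-intake distribution by the pseudo-person
#' device: for each sampled person, \code{M} independent person effects
#' \eqn{u \sim N(0, \sigma^2_u)} are drawn, the within-person variation is
#' integrated out analytically per draw (see [usual_intake_of_person()]),
#' and each pseudo-person carries weight \eqn{w_i / M}. Survey-weighted
#' summaries (mean, percentiles, prevalence below a cutoff) are computed
#' from the resulting weighted pseudo-population. Deterministic given
#' \code{seed}.
#'
#' @param fit a fitted \code{intake_fit} (or a fit reloaded with
#'   [read_fit()]).
#' @param M pseudo-person draws per sampled person.
#' @param daytype day-type weights, see [day_type_weights()].
#' @param nodes Gauss--Hermite nodes for the within-person integral.
#' @param seed RNG seed for the person-effect draws.
#' @param percentiles percentile points (in percent) to tabulate.
#' @param cutoff optional intake cutoff (e.g. the Estimated Average
#'   Requirement); if given, the weighted proportion of pseudo-persons
#'   with usual intake strictly below it is reported as
#'   \code{prevalence_below}.
#' @return object of class \code{usual_intake_dist}: list with
#'   \code{pseudo} (data frame person_id, weight, value), \code{mean},
#'   \code{percentiles} (named vector), \code{prevalence_below} (or NA),
#'   \code{cutoff}, \code{clipped_fraction}, and \code{settings}.
#' @examples
#' spec <- generator_spec(n_persons = 300, days_per_person = 1, seed = 7)
#' d <- generate_recalls(spec)$recalls
#' f <- fit_oneday(intake ~ age + group + weekend, d,
#'                 ratio = variance_ratio(2, "within_between"),
#'                 temporal = "weekend")
#' est <- estimate_distribution(f, M = 20, seed = 1,
#'                              percentiles = c(25, 50, 75))
#' est
#' @export
estimate_distribution <- function(fit, M = 100,
                                  daytype = day_type_weights(),
                                  nodes = 9, seed = 1,
                                  percentiles = 1:99, cutoff = NULL) {
  if (is.null(fit$sigma2_u) || is.null(fit$linpred)) {
    stop_model("fit does not carry variance components and linear predictors")
  }
  if (fit$sigma2_u < 0) stop_model("sigma2_u must be nonnegative")
  if (anyNA(fit$linpred$lp_weekday) || anyNA(fit$linpred$lp_weekend)) {
    stop_model("missing linear predictors in fit")
  }
  lp <- fit$linpred
  n <- nrow(lp)
  idx <- rep(seq_len(n), each = M)
  u <- with_seed(seed, stats::rnorm(n * M, 0, sqrt(fit$sigma2_u)))
  vals <- usual_intake_of_person(lp$lp_weekday[idx], lp$lp_weekend[idx], u,
                                 lambda = fit$lambda,
                                 sigma2_e = fit$sigma2_e,
                                 daytype = daytype, nodes = nodes)
  clipped <- attr(vals, "clipped_fraction")
  pseudo <- data.frame(person_id = lp$person_id[idx],
                       weight = lp$weight[idx] / M,
                       value = as.numeric(vals))
  pct <- weighted_quantile(pseudo$value, pseudo$weight, percentiles / 100)
  names(pct) <- paste0("p", percentiles)
  prev <- if (is.null(cutoff)) NA_real_ else
    weighted_mean(pseudo$value < cutoff, pseudo$weight)
  structure(list(
    pseudo = pseudo,
    mean = weighted_mean(pseudo$value, pseudo$weight),
    percentiles = pct,
    prevalence_below = prev,
    cutoff = if (is.null(cutoff)) NA_real_ else cutoff,
    clipped_fraction = clipped,
    settings = list(M = M, nodes = nodes, seed = seed,
                    daytype = daytype, method = fit$method,
                    lambda = fit$lambda)
  ), class = "usual_intake_dist")
}

#' Prevalence of usual intake below a cutoff
#'
#' Weighted proportion of the pseudo-population with usual intake strictly
#' below \code{cutoff} -- the EAR cut-point estimate of the prevalence of
#' inadequate intake when \code{cutoff} is the Estimated Average
#' Requirement.
#'
#' @param dist a [estimate_distribution()] result.
#' @param cutoff intake cutoff (> 0), original units/day.
#' @return proportion in \[0, 1\].
#' @export
prevalence_below <- function(dist, cutoff) {
  stopifnot(inherits(dist, "usual_intake_dist"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop_config("cutoff must be > 0")
  weighted_mean(dist$pseudo$value < cutoff, dist$pseudo$weight)
}

#' @export
print.usual_intake_dist <- function(x, digits = 4, ...) {
  cat("Population distribution of usual intake\n")
  cat(sprintf("  %d pseudo-persons (%d persons x M = %d), %d quadrature nodes, seed %s\n",
              nrow(x$pseudo), nrow(x$pseudo) / x$settings$M, x$settings$M,
              x$settings$nodes, format(x$settings$seed)))
  cat(sprintf("  mean = %s\n", format(x$mean, digits = digits)))
  show <- intersect(c("p5", "p25", "p50", "p75", "p95"), names(x$percentiles))
  if (!length(show)) show <- utils::head(names(x$percentiles), 5)
  print(round(x$percentiles[show], digits))
  if (!is.na(x$prevalence_below)) {
    cat(sprintf("  prevalence below %s: %.1f%%\n", format(x$cutoff),
                100 * x$prevalence_below))
  }
  if (x$clipped_fraction > 0) {
    cat(sprintf("  back-transform clipped fraction: %.3g\n", x$clipped_fraction))
  }
  invisible(x)
}

#' @export
summary.usual_intake_dist <- function(object, ...) {
  c(mean = object$mean, object$percentiles,
    prevalence_below = object$prevalence_below)
}

#' @export
mean.usual_intake_dist <- function(x, ...) x$mean

#' @export
quantile.usual_intake_dist <- function(x, probs = c(0.25, 0.5, 0.75), ...) {
  q <- weighted_quantile(x$pseudo$value, x$pseudo$weight, probs)
  names(q) <- paste0(format(100 * probs, trim = TRUE), "%")
  q
}

#' Plot the estimated usual-intake density
#'
#' Weighted kernel density of the pseudo-population usual intakes, with an
#' optional vertical line at the cutoff (EAR).
#'
#' @param x a \code{usual_intake_dist}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.usual_intake_dist <- function(x, ...) {
  w <- x$pseudo$weight / sum(x$pseudo$weight)
  d <- stats::density(x$pseudo$value, weights = w)
  graphics::plot(d, xlab = "usual intake (units/day)",
                 main = "Usual-intake distribution", ...)
  if (!is.na(x$cutoff)) graphics::abline(v = x$cutoff, col = "purple")
  invisible(x)
}
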