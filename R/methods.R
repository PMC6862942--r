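#' @export
print.intake_fit <- function(x, digits = 4, ...) {
  lab <- if (x$method == "oneday") "One-day usual-intake model (external variance ratio)"
         else "Amount-only usual-intake model (replicate recalls)"
  cat(lab, "\n")
  cat(sprintf("  n = %d record(s)%s; Box-Cox lambda = %.3g\n",
              x$n,
              if (!is.null(x$n_persons)) sprintf(" on %d persons", x$n_persons) else "",
              x$lambda))
  cat("  Coefficients (transformed scale):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  Total residual variance V = %.4g\n", x$V))
  cat(sprintf("  between-person sigma2_u = %.4g, within-person sigma2_e = %.4g\n",
              x$sigma2_u, x$sigma2_e))
  if (x$method == "oneday") {
    cat(sprintf("  split by external ratio: %s = %.4g\n",
                x$ratio$type, x$ratio$value))
  } else {
    cat(sprintf("  implied within:between ratio alpha = %.4g\n", x$alpha))
  }
  invisible(x)
}

#' @export
coef.intake_fit <- function(object, ...) object$coefficients

#' @export
residuals.intake_fit <- function(object, ...) object$residuals

#' @export
fitted.intake_fit <- function(object, ...) object$fitted.values

#' @export
summary.intake_fit <- function(object, ...) {
  out <- list(fit = object,
              variance = c(V = object$V,
                           sigma2_u = object$sigma2_u,
                           sigma2_e = object$sigma2_e,
                           alpha = if (object$method == "oneday")
                             object$alpha else object$alpha),
              diagnostics = object$diagnostics)
  class(out) <- "summary.intake_fit"
  out
}

#' @export
print.summary.intake_fit <- function(x, ...) {
  print(x$fit)
  d <- x$diagnostics
  if (d$n_shifted > 0)
    cat(sprintf("  %d zero intake(s) shifted by %.4g before transformation\n",
                d$n_shifted, d$shift))
  if (d$n_dropped > 0)
    cat(sprintf("  %d zero intake(s) dropped\n", d$n_dropped))
  if (!is.null(d$n_extra_recalls) && d$n_extra_recalls > 0)
    cat(sprintf("  %d later recall(s) ignored (one-day method uses the first recall)\n",
                d$n_extra_recalls))
  invisible(x)
}

#' Predict transformed-scale linear predictors
#'
#' Returns the covariate-determined part of the model on the transformed
#' scale for new persons, at a chosen day type ("weekday", "weekend") or
#' averaged over day types with [day_type_weights()].
#'
#' @param object a fitted \code{intake_fit}.
#' @param newdata data frame with the model covariates; defaults to the
#'   persons used in fitting.
#' @param day_type \code{"weekday"}, \code{"weekend"}, or
#'   \code{"average"}.
#' @param daytype_weights weights used when \code{day_type = "average"}.
#' @param ... unused.
#' @return numeric vector of linear predictors.
#' @export
predict.intake_fit <- function(object, newdata = NULL,
                               day_type = c("average", "weekday", "weekend"),
                               daytype_weights = day_type_weights(), ...) {
  day_type <- match.arg(day_type)
  if (is.null(newdata)) {
    lp <- object$linpred
  } else {
    X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                             newdata)
    lp <- linear_predictors(X, object$coefficients, object$temporal,
                            seq_len(nrow(X)), rep(1, nrow(X)))
  }
  switch(day_type,
         weekday = lp$lp_weekday,
         weekend = lp$lp_weekend,
         average = daytype_weights[["weekday"]] * lp$lp_weekday +
           daytype_weights[["weekend"]] * lp$lp_weekend)
}

#' Simulate recall data from a fitted model
#'
#' Draws new person effects and day-to-day errors from the fitted variance
#' components, adds them to each person's linear predictor, and
#' back-transforms to the intake scale. One simulated recall per person
#' per replicate; day types are drawn with probability 3/7 for weekend.
#'
#' @param object a fitted \code{intake_fit}.
#' @param nsim number of simulated recall sets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return data frame with columns person_id, sim, weekend, intake.
#' @export
simulate.intake_fit <- function(object, nsim = 1, seed = 1, ...) {
  lp <- object$linpred
  n <- nrow(lp)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nsim), function(s) {
      u <- stats::rnorm(n, 0, sqrt(object$sigma2_u))
      e <- stats::rnorm(n, 0, sqrt(object$sigma2_e))
      wk <- stats::rbinom(n, 1, 3 / 7)
      z <- ifelse(wk == 1, lp$lp_weekend, lp$lp_weekday) + u + e
      data.frame(person_id = lp$person_id, sim = s, weekend = wk,
                 intake = as.numeric(bc_inverse(z, object$lambda)))
    }))
    out
  })
}
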