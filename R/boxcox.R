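#' Box-Cox transformation
#'
#' The power transformation \eqn{g(x; \lambda) = (x^\lambda - 1)/\lambda},
#' with \eqn{\lambda = 0} meaning the natural logarithm. Used throughout to
#' bring skewed 24-hour recall amounts close to normality before the
#' measurement-error model is fitted.
#'
#' The implementation uses \code{expm1} so the transform is numerically
#' continuous in \eqn{\lambda} at 0.
#'
#' @param x positive intake amounts.
#' @param lambda transformation parameter (unitless).
#' @return transformed values, same length as \code{x}.
#' @seealso [bc_inverse()], [select_lambda()]
#' @examples
#' bc_transform(4, 0.5)   # 2
#' bc_transform(exp(1), 0) # 1
#' @export
bc_transform <- function(x, lambda) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop_data("Box-Cox transform requires positive intakes; offending record(s): ",
              paste(utils::head(bad, 5L), collapse = ", "),
              if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L))
  }
  if (lambda == 0) log(x) else expm1(lambda * log(x)) / lambda
}

#' Inverse Box-Cox transformation
#'
#' Maps a transformed-scale value back to the original intake scale:
#' \eqn{(\lambda y + 1)^{1/\lambda}} for \eqn{\lambda \neq 0}, \eqn{e^y}
#' for \eqn{\lambda = 0}. Arguments for which \eqn{\lambda y + 1 \le 0}
#' (outside the image of the transform) are clipped to 0, since an intake
#' cannot be negative; the number of clipped values is attached as the
#' \code{"n_clipped"} attribute so downstream summaries can report the
#' clipped fraction.
#'
#' @param y transformed-scale values.
#' @param lambda transformation parameter.
#' @return intake amounts (>= 0) with attribute \code{n_clipped}.
#' @examples
#' bc_inverse(2, 0.5)  # 4
#' bc_inverse(-10, 0.5) # 0, clipped
#' @export
bc_inverse <- function(y, lambda) {
  if (lambda == 0) {
    out <- exp(y)
    attr(out, "n_clipped") <- 0L
    return(out)
  }
  base <- lambda * y + 1
  clipped <- base <= 0
  out <- numeric(length(y))
  out[!clipped] <- exp(log(base[!clipped]) / lambda)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Candidate grid for the Box-Cox parameter
#'
#' The default grid runs from 0 (natural log) to 1 in steps of 0.01,
#' matching the transformation search used by the one-day fitting
#' procedure. The grid always contains 0 exactly.
#'
#' @param lo,hi grid endpoints (defaults 0 and 1).
#' @param step grid step (> 0, default 0.01).
#' @return numeric vector of class \code{lambda_grid}.
#' @export
lambda_grid <- function(lo = 0, hi = 1, step = 0.01) {
  if (lo < 0) stop_config("lambda grid lower endpoint must be >= 0")
  if (step <= 0) stop_config("lambda grid step must be > 0")
  if (hi <= lo) stop_config("lambda grid needs hi > lo")
  g <- seq(lo, hi, by = step)
  # the log case must be on the grid exactly when lo == 0
  g[abs(g) < 1e-12] <- 0
  structure(g, class = c("lambda_grid", class(g)))
}

#' Linearity of the weighted normal probability plot
#'
#' Computes the survey-weighted empirical percentiles 1--99 of a residual
#' vector, pairs them with the standard-normal quantiles
#' \eqn{\Phi^{-1}(p/100)}, and returns the squared Pearson correlation of
#' the 99 pairs. This is the normality score maximised when selecting the
#' Box-Cox parameter: a perfectly normal residual distribution gives an
#' R-squared close to 1, skewness pulls it down.
#'
#' @param residuals transformed-scale residuals.
#' @param weights survey weights (default equal).
#' @return R-squared in \[0, 1\].
#' @export
normal_plot_r2 <- function(residuals, weights = rep(1, length(residuals))) {
  if (length(residuals) < 100L) {
    warning("fewer than 100 residuals: percentiles 1-99 are heavily interpolated")
  }
  p <- (1:99) / 100
  q_emp <- weighted_quantile(residuals, weights, p)
  if (stats::sd(q_emp) == 0) {
    stop_data("residuals have zero spread: normal probability plot R^2 is undefined")
  }
  stats::cor(q_emp, stats::qnorm(p))^2
}

#' Select a Box-Cox parameter by probability-plot linearity
#'
#' For each candidate \eqn{\lambda} on the grid the intakes are
#' transformed, the survey-weighted regression of transformed intake on
#' the covariates is refitted, and the linearity of the weighted normal
#' probability plot of its residuals is scored with [normal_plot_r2()].
#' The selected \eqn{\lambda} maximises the R-squared; exact ties (to
#' within 1e-12) go to the smaller \eqn{\lambda}.
#'
#' Requires single-recall data (one row per person); intended for the
#' one-day workflow where the amount-only likelihood is unavailable.
#'
#' @param formula model formula, response = intake column.
#' @param data data frame with one row per person.
#' @param weights survey-weight column name, or a numeric vector; NULL for
#'   equal weights.
#' @param grid candidate grid from [lambda_grid()].
#' @return object of class \code{lambda_selection}: list with elements
#'   \code{lambda} (the selected value), \code{r_squared}, and
#'   \code{profile} (data frame of lambda, r2 over the whole grid; NA r2
#'   marks a skipped grid point).
#' @export
select_lambda <- function(formula, data, weights = NULL, grid = lambda_grid()) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  w <- resolve_weights(weights, data, nrow(X))
  sel <- select_lambda_core(y, X, w, grid)
  structure(sel, class = "lambda_selection")
}

# Core grid scan shared with fit_oneday(); y must already be positive.
select_lambda_core <- function(y, X, w, grid) {
  r2 <- rep(NA_real_, length(grid))
  logy <- log(y)
  for (i in seq_along(grid)) {
    lam <- grid[i]
    z <- if (lam == 0) logy else expm1(lam * logy) / lam
    fit <- stats::lm.wfit(X, z, w)
    r2[i] <- tryCatch(
      suppressWarnings(normal_plot_r2(fit$residuals, w)),
      error = function(e) NA_real_
    )
  }
  if (all(is.na(r2))) stop_model("Box-Cox selection failed at every grid point")
  if (anyNA(r2)) {
    warning(sprintf("%d lambda grid point(s) skipped (degenerate residuals)",
                    sum(is.na(r2))))
  }
  best <- max(r2, na.rm = TRUE)
  # ties to machine precision resolved toward the smaller lambda
  lam_hat <- min(grid[!is.na(r2) & r2 >= best - 1e-12])
  list(lambda = lam_hat,
       r_squared = r2[match(lam_hat, grid)],
       profile = data.frame(lambda = as.numeric(grid), r2 = r2))
}

#' @export
print.lambda_selection <- function(x, ...) {
  cat("Box-Cox parameter selection (normal probability plot linearity)\n")
  cat(sprintf("  lambda = %.2f  (R^2 = %.5f over %d grid points)\n",
              x$lambda, x$r_squared, nrow(x$profile)))
  invisible(x)
}

#' @export
plot.lambda_selection <- function(x, ...) {
  graphics::plot(x$profile$lambda, x$profile$r2, type = "l",
                 xlab = expression(lambda),
                 ylab = expression(R^2 ~ "of normal probability plot"), ...)
  graphics::abline(v = x$lambda, lty = 2)
  invisible(x)
}

# Accept weights as a column name, a numeric vector, or NULL (equal).
resolve_weights <- function(weights, data, n) {
  if (is.null(weights)) return(rep(1, n))
  if (is.character(weights)) {
    if (!weights %in% names(data)) {
      stop_data("weight column '", weights, "' not found in data")
    }
    weights <- data[[weights]]
  }
  if (length(weights) != n) stop_data("weights length does not match data")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop_data("weights must be finite and nonnegative")
  }
  weights
}
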