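#' Fit the amount-only mixed model to replicate-recall data
#'
#' Fits the replicate-recall measurement-error model
#' \deqn{g(R_{ij}; \lambda) = \beta_0 + \sum_k \beta_k X_{ki} +
#'       \sum_l \beta_l Z_{lij} + u_i + e_{ij}}
#' with a person random intercept \eqn{u_i \sim N(0, \sigma^2_u)} and
#' day-to-day error \eqn{e_{ij} \sim N(0, \sigma^2_e)}, by maximum
#' likelihood on Box-Cox transformed intakes. The Box-Cox parameter is
#' profiled over the same 0--1 grid used by the one-day method: for each
#' candidate \eqn{\lambda} the weighted ML of the random-intercept model
#' is maximised (a one-dimensional search over the variance ratio with the
#' regression coefficients and scale profiled out in closed form), the
#' transformation Jacobian \eqn{(\lambda - 1)\sum w \log R} is added so
#' likelihoods are comparable across \eqn{\lambda}, and the grid maximiser
#' is returned.
#'
#' Survey weights enter as frequency-style weights in the likelihood
#' (each person's log-likelihood contribution is multiplied by their
#' weight); design-based uncertainty is carried by replicate-weight reruns,
#' not by the weights themselves. At least one person must have two or
#' more recalls, otherwise the variance components cannot be separated.
#' The implied within:between ratio \eqn{\hat\alpha =
#' \hat\sigma^2_e/\hat\sigma^2_u} is the natural "unbiased external ratio"
#' to feed into [fit_oneday()] on single-day data.
#'
#' @inheritParams fit_oneday
#' @return an object of class \code{c("amount_fit", "intake_fit")} with
#'   components \code{lambda}, \code{lambda_profile} (profile
#'   log-likelihood over the grid), \code{coefficients}, \code{sigma2_u},
#'   \code{sigma2_e}, \code{V} (their sum), \code{alpha}
#'   (\eqn{\hat\sigma^2_e/\hat\sigma^2_u}), \code{loglik},
#'   \code{boundary} flag, \code{linpred}, \code{residuals},
#'   \code{diagnostics}.
#' @seealso [extract_ratio()], [fit_oneday()], [estimate_distribution()]
#' @examples
#' spec <- generator_spec(n_persons = 250, days_per_person = 2, seed = 11)
#' d <- generate_recalls(spec)$recalls
#' f <- fit_amount_only(intake ~ age + group + weekend, d,
#'                      temporal = "weekend",
#'                      grid = lambda_grid(step = 0.05))
#' extract_ratio(f)
#' @export
fit_amount_only <- function(formula, data,
                            id = "person_id", day = "day",
                            weights = if ("weight" %in% names(data)) "weight" else NULL,
                            temporal = character(),
                            lambda = NULL, grid = lambda_grid(),
                            zero_handling = c("shift", "drop")) {
  zero_handling <- match.arg(zero_handling)
  cl <- match.call()

  if (!id %in% names(data)) stop_data("id column '", id, "' not found")
  w_all <- resolve_weights(weights, data, nrow(data))
  data$.w <- w_all
  if (day %in% names(data)) {
    data <- data[order(data[[id]], data[[day]]), , drop = FALSE]
  } else {
    data <- data[order(data[[id]]), , drop = FALSE]
  }

  prep <- prepare_intakes(data, formula, zero_handling)
  data <- prep$data
  w <- data$.w

  f <- factor(data[[id]], levels = unique(data[[id]]))
  fi <- as.integer(f)
  ni <- tabulate(fi)
  if (max(ni) < 2L) {
    stop_model("cannot separate variance components: no person has >= 2 recalls")
  }

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) {
    stop_data(sprintf("need at least %d rows to fit %d coefficients; have %d",
                      p + 2L, p, n))
  }
  check_design(X, temporal, formula)

  # person-level weights for the log-determinant term (weights are assumed
  # constant within person; the first row's value is used)
  wi <- w[!duplicated(fi)]
  Nw <- sum(w)
  logy <- log(y)
  jac_base <- sum(w * logy)
  sw <- sqrt(w)

  log_rho_bounds <- c(log(1e-8), log(1e8))

  # Profile -2 log-likelihood (up to a constant) at a given variance ratio
  # rho = sigma2_u / sigma2_e, for transformed response z.
  prof_dev <- function(log_rho, z) {
    rho <- exp(log_rho)
    s <- 1 + ni * rho
    theta <- 1 - 1 / sqrt(s)
    zbar <- rowsum(z, fi) / ni
    zs <- z - theta[fi] * zbar[fi]
    Xbar <- rowsum(X, fi) / ni
    Xs <- X - theta[fi] * Xbar[fi, , drop = FALSE]
    ft <- stats::.lm.fit(Xs * sw, zs * sw)
    rss <- sum(ft$residuals^2)
    Nw * log(rss / Nw) + sum(wi * log(s))
  }

  fit_at_lambda <- function(lam) {
    z <- if (lam == 0) logy else expm1(lam * logy) / lam
    opt <- stats::optimize(prof_dev, interval = log_rho_bounds, z = z,
                           tol = 1e-6)
    ll <- -0.5 * (opt$objective + Nw * (1 + log(2 * pi))) +
      (lam - 1) * jac_base
    list(log_rho = opt$minimum, loglik = ll)
  }

  if (is.null(lambda)) {
    prof <- lapply(as.numeric(grid), fit_at_lambda)
    ll <- vapply(prof, `[[`, numeric(1), "loglik")
    best <- max(ll)
    k <- which(ll >= best - 1e-9)[1L]  # ties toward the smaller lambda
    lambda <- as.numeric(grid)[k]
    inner <- prof[[k]]
    lambda_profile <- data.frame(lambda = as.numeric(grid), loglik = ll)
  } else {
    inner <- fit_at_lambda(lambda)
    lambda_profile <- NULL
  }

  rho <- exp(inner$log_rho)
  boundary <- inner$log_rho <= log_rho_bounds[1] + 0.02 ||
    inner$log_rho >= log_rho_bounds[2] - 0.02

  # final GLS fit at the selected (lambda, rho)
  z <- bc_transform(y, lambda)
  s <- 1 + ni * rho
  theta <- 1 - 1 / sqrt(s)
  zbar <- rowsum(z, fi) / ni
  Xbar <- rowsum(X, fi) / ni
  ft <- stats::lm.wfit(X - theta[fi] * Xbar[fi, , drop = FALSE],
                       z - theta[fi] * zbar[fi], w)
  sigma2_e <- sum(w * ft$residuals^2) / Nw
  sigma2_u <- rho * sigma2_e
  beta <- ft$coefficients

  if (inner$log_rho <= log_rho_bounds[1] + 0.02) {
    warning("sigma2_u estimated at the boundary 0; the within:between ratio is infinite")
    alpha <- Inf
  } else {
    alpha <- sigma2_e / sigma2_u
    if (inner$log_rho >= log_rho_bounds[2] - 0.02) {
      warning("sigma2_e estimated at the boundary 0")
    }
  }

  # per-person linear predictors from each person's person-level covariates
  first <- !duplicated(fi)
  lp <- linear_predictors(X[first, , drop = FALSE], beta, temporal,
                          data[[id]][first], w[first])

  structure(list(
    method = "amount_only",
    call = cl, formula = formula, temporal = temporal,
    lambda = lambda, lambda_profile = lambda_profile,
    coefficients = beta,
    V = sigma2_u + sigma2_e,
    sigma2_u = sigma2_u,
    sigma2_e = sigma2_e,
    alpha = alpha,
    boundary = boundary,
    loglik = inner$loglik,
    linpred = lp,
    residuals = drop(z - X %*% beta),
    fitted.values = drop(X %*% beta),
    n = n, n_persons = length(ni), n_eff = Nw^2 / sum(w^2), df = p,
    diagnostics = list(n_shifted = prep$n_shifted,
                       n_dropped = prep$n_dropped,
                       shift = prep$shift)
  ), class = c("amount_fit", "intake_fit"))
}

#' Extract the fitted variance ratio from an amount-only fit
#'
#' Computes the within-person to between-person variance ratio implied by
#' the fitted components, in any of the three conventions, for use as the
#' external ratio of the one-day method.
#'
#' @param fit an [fit_amount_only()] result.
#' @param type requested ratio convention (see [variance_ratio()]).
#' @return a [variance_ratio()].
#' @examples
#' # Components like those of a vitamin A amount-only fit:
#' # sigma2_u = 5.220, sigma2_e = 10.450 give alpha = 2.002
#' @export
extract_ratio <- function(fit, type = "within_between") {
  stopifnot(inherits(fit, "amount_fit"))
  if (fit$boundary || !is.finite(fit$alpha) || fit$sigma2_u <= 0) {
    stop_model("variance components were estimated at a boundary; the ratio is degenerate")
  }
  convert_ratio(variance_ratio(fit$alpha, "within_between"), type)
}
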