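#' Fit the one-day usual-intake model to single-recall data
#'
#' Fits the single-recall measurement-error model
#' \deqn{g(R_i; \lambda) = \beta_0 + \sum_k \beta_k X_{ki} +
#'       \sum_l \beta_l Z_{li} + d_i}
#' where \eqn{g} is the Box-Cox transformation, \eqn{X} are person-level
#' covariates (e.g. age, race/ethnicity indicators), \eqn{Z} are temporal
#' covariates (e.g. a weekend indicator), and \eqn{d_i = u_i + e_i} is the
#' combined person effect plus day-to-day error. With a single recall per
#' person only the total residual variance \eqn{V = var(d_i)} is
#' estimable; an external variance ratio supplies the split into
#' between-person (\eqn{\sigma^2_u}) and within-person (\eqn{\sigma^2_e})
#' components via [split_variance()].
#'
#' The transformation parameter is chosen by maximising the linearity of
#' the weighted normal probability plot of residuals over a grid (see
#' [select_lambda()]), refitting the survey-weighted regression at each
#' candidate. Coefficients come from survey-weighted least squares; the
#' total variance is the weighted mean squared residual with an effective
#' degrees-of-freedom correction, \eqn{n_{eff} = (\sum w)^2 / \sum w^2}.
#'
#' If the data contain several recalls per person only the first (lowest
#' day index) is used, with a warning. Zero intakes (permitted for under
#' 5\% of records of a nearly-daily component) are shifted by half the
#' smallest positive observed intake before transformation, or dropped if
#' \code{zero_handling = "drop"}; either way the count is recorded in the
#' fit's diagnostics.
#'
#' @param formula model formula; the response names the intake column.
#' @param data data frame of person-day recall records.
#' @param ratio external [variance_ratio()].
#' @param id,day column names for the person identifier and recall day
#'   index. The \code{day} column may be absent when each person appears
#'   once.
#' @param weights survey-weight column name (default \code{"weight"} if
#'   present, else equal weights), or a numeric vector.
#' @param temporal character vector naming the formula variables that vary
#'   by day type; they must be numeric 0/1 indicators (0 = weekday,
#'   1 = weekend). Linear predictors are stored for every person at both
#'   levels so the distribution step can average over day types.
#' @param lambda fix the Box-Cox parameter to this value instead of
#'   selecting it from \code{grid}.
#' @param grid candidate grid from [lambda_grid()].
#' @param zero_handling how to treat zero intakes: \code{"shift"}
#'   (default) or \code{"drop"}.
#' @return an object of class \code{c("oneday_fit", "intake_fit")}; a list
#'   with components \code{lambda}, \code{lambda_profile},
#'   \code{coefficients}, \code{V} (total residual variance),
#'   \code{sigma2_u}, \code{sigma2_e}, \code{ratio}, \code{linpred}
#'   (per-person weekday/weekend linear predictors with weights),
#'   \code{residuals}, \code{diagnostics}.
#' @seealso [estimate_distribution()] to turn the fit into a usual-intake
#'   distribution; [fit_amount_only()] for replicate-recall data.
#' @examples
#' spec <- generator_spec(n_persons = 300, days_per_person = 1, seed = 7)
#' d <- generate_recalls(spec)$recalls
#' f <- fit_oneday(intake ~ age + group + weekend, d,
#'                 ratio = variance_ratio(2, "within_between"),
#'                 temporal = "weekend")
#' f
#' @export
fit_oneday <- function(formula, data, ratio,
                       id = "person_id", day = "day",
                       weights = if ("weight" %in% names(data)) "weight" else NULL,
                       temporal = character(),
                       lambda = NULL, grid = lambda_grid(),
                       zero_handling = c("shift", "drop")) {
  stopifnot(inherits(ratio, "variance_ratio"))
  zero_handling <- match.arg(zero_handling)
  cl <- match.call()

  if (!id %in% names(data)) stop_data("id column '", id, "' not found")
  w_all <- resolve_weights(weights, data, nrow(data))
  data$.w <- w_all

  # keep only the first recall per person
  if (day %in% names(data)) {
    data <- data[order(data[[id]], data[[day]]), , drop = FALSE]
  } else {
    data <- data[order(data[[id]]), , drop = FALSE]
  }
  dup <- duplicated(data[[id]])
  n_extra <- sum(dup)
  if (n_extra > 0L) {
    warning(sprintf(
      "data contain repeated recalls; using only the first recall for each of %d person(s)",
      length(unique(data[[id]][dup]))))
    data <- data[!dup, , drop = FALSE]
  }

  prep <- prepare_intakes(data, formula, zero_handling)
  data <- prep$data
  w <- data$.w

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) {
    stop_data(sprintf("need at least %d rows to fit %d coefficients; have %d",
                      p + 2L, p, n))
  }
  check_design(X, temporal, formula)

  if (is.null(lambda)) {
    sel <- select_lambda_core(y, X, w, grid)
    lambda <- sel$lambda
    profile <- sel$profile
  } else {
    profile <- NULL
  }

  z <- bc_transform(y, lambda)
  fit <- stats::lm.wfit(X, z, w)
  beta <- fit$coefficients
  res <- fit$residuals
  n_eff <- sum(w)^2 / sum(w^2)
  if (n_eff <= p) stop_model("effective sample size does not exceed the number of coefficients")
  V <- sum(w * res^2) / sum(w) * n_eff / (n_eff - p)
  comp <- split_variance(V, ratio)

  lp <- linear_predictors(X, beta, temporal, data[[id]], w)

  structure(list(
    method = "oneday",
    call = cl, formula = formula, temporal = temporal,
    lambda = lambda, lambda_profile = profile,
    coefficients = beta,
    V = V,
    sigma2_u = unname(comp["var_between"]),
    sigma2_e = unname(comp["var_within"]),
    ratio = ratio,
    alpha = convert_ratio(ratio, "within_between")$value,
    linpred = lp,
    residuals = res,
    fitted.values = z - res,
    n = n, n_eff = n_eff, df = p,
    diagnostics = list(n_shifted = prep$n_shifted,
                       n_dropped = prep$n_dropped,
                       shift = prep$shift,
                       n_extra_recalls = n_extra)
  ), class = c("oneday_fit", "intake_fit"))
}

# Zero-intake handling shared by both fitters: nearly-daily components may
# contain a small fraction of zeros, which Box-Cox cannot take.
prepare_intakes <- function(data, formula, zero_handling) {
  resp <- all.vars(formula)[1L]
  if (!resp %in% names(data)) stop_data("intake column '", resp, "' not found")
  intake <- data[[resp]]
  if (any(!is.finite(intake)) || any(intake < 0)) {
    bad <- which(!is.finite(intake) | intake < 0)
    stop_data("intakes must be finite and nonnegative; offending record(s): ",
              paste(utils::head(bad, 5L), collapse = ", "))
  }
  zero <- intake == 0
  n_shifted <- 0L; n_dropped <- 0L; shift <- 0
  if (any(zero)) {
    if (mean(zero) >= 0.05) {
      stop_data(sprintf(
        "%.1f%% of intakes are zero: the component is not nearly-daily consumed (< 5%% zeros required)",
        100 * mean(zero)))
    }
    if (zero_handling == "shift") {
      shift <- min(intake[!zero]) / 2
      data[[resp]][zero] <- shift
      n_shifted <- sum(zero)
    } else {
      data <- data[!zero, , drop = FALSE]
      n_dropped <- sum(zero)
    }
  }
  list(data = data, n_shifted = n_shifted, n_dropped = n_dropped, shift = shift)
}

# Rank/collinearity check that names the offending columns, and validation
# of the temporal covariates as 0/1 indicators present in the formula.
check_design <- function(X, temporal, formula) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_data("collinear covariates: ", paste(dropped, collapse = ", "))
  }
  for (tv in temporal) {
    if (!tv %in% colnames(X)) {
      stop_config("temporal covariate '", tv,
                  "' must appear as a numeric 0/1 column of the model matrix")
    }
    vals <- unique(X[, tv])
    if (!all(vals %in% c(0, 1))) {
      stop_config("temporal covariate '", tv, "' must be a 0/1 indicator")
    }
  }
  invisible(TRUE)
}

# Per-person linear predictors at both day types: temporal indicator
# columns forced to 0 (weekday) and 1 (weekend).
linear_predictors <- function(X, beta, temporal, ids, w) {
  Xwd <- X; Xwe <- X
  if (length(temporal)) {
    Xwd[, temporal] <- 0
    Xwe[, temporal] <- 1
  }
  data.frame(person_id = ids,
             weight = w,
             lp_weekday = drop(Xwd %*% beta),
             lp_weekend = drop(Xwe %*% beta),
             stringsAsFactors = FALSE)
}
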