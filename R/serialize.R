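#' Save a fitted model to plain-text parameter files
#'
#' Writes the quantities the distribution step needs -- transformation
#' parameter, coefficients, variance components, ratio, diagnostics -- to
#' a YAML parameter file, and the per-person linear predictors to a CSV
#' alongside it (\code{<path without extension>_linpred.csv}). The pair
#' is the hand-off between the fitting stage and the distribution stage,
#' and [read_fit()] reconstructs a fit either [estimate_distribution()]
#' or [run_sweep()] can consume, whichever method produced it.
#'
#' @param fit a fitted \code{intake_fit}.
#' @param path parameter-file path (e.g. \code{"fit_params.yml"}).
#' @return invisibly, the two file paths written.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "intake_fit"))
  lp_path <- paste0(sub("\\.[A-Za-z]+$", "", path), "_linpred.csv")
  params <- list(
    method = fit$method,
    lambda = fit$lambda,
    coefficients = as.list(fit$coefficients),
    V = fit$V,
    var_between = fit$sigma2_u,
    var_within = fit$sigma2_e,
    ratio_type = if (!is.null(fit$ratio)) fit$ratio$type else "within_between",
    ratio_value = if (!is.null(fit$ratio)) fit$ratio$value else fit$alpha,
    temporal = as.list(fit$temporal),
    n = fit$n,
    diagnostics = fit$diagnostics[c("n_shifted", "n_dropped")],
    linpred_file = basename(lp_path)
  )
  yaml::write_yaml(params, path, precision = 12)
  utils::write.csv(fit$linpred, lp_path, row.names = FALSE)
  invisible(c(path, lp_path))
}

#' Reload a fitted model from its parameter files
#'
#' @param path path previously given to [write_fit()].
#' @return object of class \code{intake_fit} (plus the method-specific
#'   class) carrying everything [estimate_distribution()] needs.
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop_data("parameter file not found: ", path)
  params <- yaml::read_yaml(path)
  lp_path <- file.path(dirname(path), params$linpred_file)
  if (!file.exists(lp_path)) stop_data("linear-predictor file not found: ", lp_path)
  lp <- utils::read.csv(lp_path)
  cls <- if (identical(params$method, "oneday")) "oneday_fit" else "amount_fit"
  structure(list(
    method = params$method,
    lambda = params$lambda,
    coefficients = unlist(params$coefficients),
    V = params$V,
    sigma2_u = params$var_between,
    sigma2_e = params$var_within,
    ratio = variance_ratio(params$ratio_value, params$ratio_type),
    alpha = convert_ratio(variance_ratio(params$ratio_value,
                                         params$ratio_type),
                          "within_between")$value,
    temporal = unlist(params$temporal),
    linpred = lp,
    n = params$n,
    diagnostics = params$diagnostics,
    boundary = FALSE
  ), class = c(cls, "intake_fit"))
}
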