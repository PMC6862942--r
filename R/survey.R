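#' Balanced repeated replication standard error
#'
#' Classical BRR variance estimate from replicate-weight re-estimates:
#' \deqn{SE = \sqrt{\frac{1}{R (1-F)^2} \sum_{r=1}^R
#'   (\hat\theta_r - \hat\theta)^2}}
#' where \eqn{F} is the Fay coefficient (0 gives classical BRR with
#' doubled/zeroed half-samples; NHANES releases typically use Fay
#' \eqn{F = 0.3}, so set \code{fay} to the value matching how the
#' replicate weights were built).
#'
#' @param full_estimate full-sample estimate \eqn{\hat\theta}.
#' @param replicate_estimates vector of per-replicate estimates
#'   \eqn{\hat\theta_r}.
#' @param fay Fay coefficient in \[0, 1).
#' @return the standard error.
#' @examples
#' brr_se(10, c(9, 11))           # 1
#' brr_se(10, c(9, 11), fay = 0.5) # 2
#' @export
brr_se <- function(full_estimate, replicate_estimates, fay = 0) {
  if (fay < 0 || fay >= 1) stop_config("Fay coefficient must lie in [0, 1)")
  if (!length(replicate_estimates)) stop_config("need at least one replicate estimate")
  if (any(!is.finite(replicate_estimates)) || !is.finite(full_estimate)) {
    stop_data("estimates must be finite")
  }
  sqrt(mean((replicate_estimates - full_estimate)^2) / (1 - fay)^2)
}

#' Recompute a statistic under each set of replicate weights
#'
#' Runs an estimator once with the full-sample weights and once per
#' replicate-weight column, returning everything [brr_se()] needs. The
#' estimator receives the data and a weight vector and must return a named
#' numeric vector of statistics.
#'
#' @param data data frame holding a full-sample weight column and
#'   replicate-weight columns.
#' @param statistic function(data, weights) -> named numeric vector.
#' @param weight_col full-sample weight column name.
#' @param rep_prefix prefix of the replicate-weight columns
#'   (e.g. \code{"repwt_"}).
#' @param fay Fay coefficient used when the replicate weights were built.
#' @return object of class \code{replicate_estimates}: list with
#'   \code{full} (named vector), \code{replicates} (R x k matrix),
#'   \code{se} (named vector of BRR standard errors), \code{fay}.
#' @export
brr_replicates <- function(data, statistic, weight_col = "weight",
                           rep_prefix = "repwt_", fay = 0) {
  rep_cols <- grep(paste0("^", rep_prefix), names(data), value = TRUE)
  if (!length(rep_cols)) stop_data("no replicate-weight columns with prefix '",
                                   rep_prefix, "'")
  full <- statistic(data, data[[weight_col]])
  reps <- vapply(rep_cols, function(cc) statistic(data, data[[cc]]),
                 numeric(length(full)))
  reps <- t(matrix(reps, nrow = length(full),
                   dimnames = list(names(full), rep_cols)))
  se <- vapply(seq_along(full), function(j) brr_se(full[j], reps[, j], fay),
               numeric(1))
  names(se) <- names(full)
  structure(list(full = full, replicates = reps, se = se, fay = fay,
                 R = length(rep_cols)),
            class = "replicate_estimates")
}

#' @export
print.replicate_estimates <- function(x, ...) {
  cat(sprintf("BRR replicate estimates (R = %d, Fay = %g)\n", x$R, x$fay))
  print(rbind(estimate = x$full, se = x$se))
  invisible(x)
}

#' Equivalence margin for a statistic
#'
#' Margins used when testing whether two methods' estimates are
#' equivalent: 5\% of the reference (amount-only) estimate for means and
#' percentiles, and an absolute 0.5 percentage points for prevalence
#' estimates (prevalences compared on the percent scale).
#'
#' @param statistic_kind one of \code{"mean"}, \code{"percentile"},
#'   \code{"prevalence"}.
#' @param reference_value the reference estimate (needed for the relative
#'   margins).
#' @return the margin, in the statistic's units.
#' @examples
#' margin_for("percentile", 647.4) # 32.37
#' margin_for("prevalence")        # 0.5 percentage points
#' @export
margin_for <- function(statistic_kind, reference_value = NULL) {
  if (!statistic_kind %in% c("mean", "percentile", "prevalence")) {
    stop_config("unknown statistic kind '", statistic_kind, "'")
  }
  if (statistic_kind == "prevalence") return(0.5)
  if (is.null(reference_value) || reference_value <= 0) {
    stop_config("relative margins need a positive reference value")
  }
  0.05 * reference_value
}

#' Two one-sided tests of equivalence
#'
#' z-based TOST of \eqn{H_0: |a - b| \ge margin} against equivalence. The
#' reported p-value is the larger of the two one-sided p-values;
#' equivalence is declared when it falls below 0.05.
#'
#' @param a,b the two estimates.
#' @param se_diff standard error of the difference \eqn{a - b} (> 0).
#' @param margin equivalence margin (> 0).
#' @param level test level (default 0.05).
#' @return object of class \code{equivalence_result}: list with
#'   \code{estimate_a}, \code{estimate_b}, \code{difference},
#'   \code{se_difference}, \code{margin}, \code{p_value},
#'   \code{equivalent}.
#' @examples
#' tost_equivalence(10, 10.1, se_diff = 0.2, margin = 1)
#' @export
tost_equivalence <- function(a, b, se_diff, margin, level = 0.05) {
  if (margin <= 0) stop_config("equivalence margin must be > 0")
  if (se_diff <= 0) stop_config("se_diff must be > 0")
  d <- a - b
  p_lower <- stats::pnorm((d + margin) / se_diff, lower.tail = FALSE)
  p_upper <- stats::pnorm((d - margin) / se_diff)
  p <- max(p_lower, p_upper)
  structure(list(estimate_a = a, estimate_b = b, difference = d,
                 se_difference = se_diff, margin = margin,
                 p_value = p, equivalent = p < level, level = level),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "TOST equivalence: diff = %.4g (SE %.4g), margin = %.4g, p = %.4g -> %s\n",
    x$difference, x$se_difference, x$margin, x$p_value,
    if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}
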