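#' Weighted quantiles of a sample
#'
#' Quantiles of a weighted sample, defined through the weighted empirical
#' CDF with linear interpolation between order statistics. Plotting
#' positions are \code{(C_k - w_k) / (C_n - w_n)} where \code{C_k} is the
#' cumulative weight up to the k-th order statistic; with equal weights
#' this reduces to the familiar \code{(k - 1)/(n - 1)} rule (quantile
#' type 7).
#'
#' @param x numeric vector of observations.
#' @param w nonnegative weights, recycled if of length one.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of \code{probs}.
#' @examples
#' weighted_quantile(1:10, rep(1, 10), c(0.25, 0.5, 0.75))
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs = 0.5) {
  if (length(w) == 1L) w <- rep(w, length(x))
  stopifnot(length(x) == length(w), all(is.finite(x)), all(w >= 0))
  if (any(!is.finite(w))) stop("weights must be finite")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  n <- length(x)
  if (n == 0L) stop("no observations with positive weight")
  if (n == 1L) return(rep(x, length(probs)))
  o <- order(x)
  xs <- x[o]; ws <- w[o]
  cw <- cumsum(ws)
  pos <- (cw - ws) / (cw[n] - ws[n])
  stats::approx(pos, xs, xout = probs, rule = 2, ties = "ordered")$y
}

#' Weighted mean and variance helpers
#'
#' @param x numeric vector.
#' @param w nonnegative weights.
#' @return `weighted_mean` returns the weighted average; `weighted_var`
#'   the weighted variance with effective-sample-size correction
#'   \code{n_eff = (sum w)^2 / sum w^2}.
#' @keywords internal
#' @noRd
weighted_mean <- function(x, w) sum(w * x) / sum(w)

#' @noRd
weighted_var <- function(x, w) {
  m <- weighted_mean(x, w)
  neff <- sum(w)^2 / sum(w^2)
  sum(w * (x - m)^2) / sum(w) * neff / (neff - 1)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Classed conditions so the command-line layer can map errors to exit codes.
stop_config <- function(...) {
  stop(structure(class = c("usualintake_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("usualintake_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_model <- function(...) {
  stop(structure(class = c("usualintake_model_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
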