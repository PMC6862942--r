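#' External variance ratio
#'
#' A scalar relating the within-person (day-to-day, \eqn{\sigma^2_e}) and
#' between-person (\eqn{\sigma^2_u}) variance components on the
#' transformed scale. Three conventions circulate in the literature and
#' all are supported:
#' \describe{
#'   \item{\code{within_between} (\eqn{\alpha})}{within / between, any
#'     positive value;}
#'   \item{\code{within_total} (\eqn{\beta})}{within / total, in (0, 1);}
#'   \item{\code{between_total} (\eqn{\gamma})}{between / total, in (0, 1).}
#' }
#' When only a single recall per person is available the components cannot
#' be separated from the data, and an external ratio of one of these types
#' (taken from a comparable study with replicate recalls) supplies the
#' split.
#'
#' @param value the ratio (unitless).
#' @param type one of \code{"within_between"}, \code{"within_total"},
#'   \code{"between_total"}.
#' @return object of class \code{variance_ratio}.
#' @examples
#' variance_ratio(2, "within_between")
#' @export
variance_ratio <- function(value, type = c("within_between", "within_total",
                                           "between_total")) {
  type <- match.arg(type)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop_config("variance ratio must be a single finite number")
  }
  if (type == "within_between" && value <= 0) {
    stop_config("within:between ratio (alpha) must be > 0")
  }
  if (type %in% c("within_total", "between_total") &&
      (value <= 0 || value >= 1)) {
    stop_config(type, " ratio must lie strictly in (0, 1)")
  }
  structure(list(value = value, type = type), class = "variance_ratio")
}

#' @export
print.variance_ratio <- function(x, ...) {
  lab <- c(within_between = "within-person : between-person (alpha)",
           within_total = "within-person : total (beta)",
           between_total = "between-person : total (gamma)")[x$type]
  cat(sprintf("Variance ratio: %s = %g\n", lab, x$value))
  invisible(x)
}

#' Convert a variance ratio between conventions
#'
#' Algebraic conversion between the three ratio conventions, e.g.
#' \eqn{\alpha = \beta/(1-\beta) = (1-\gamma)/\gamma}. Round-trips
#' exactly.
#'
#' @param ratio a [variance_ratio()].
#' @param target_type the requested convention.
#' @return a \code{variance_ratio} of the requested type.
#' @examples
#' convert_ratio(variance_ratio(2, "within_between"), "within_total")
#' @export
convert_ratio <- function(ratio, target_type = c("within_between",
                                                 "within_total",
                                                 "between_total")) {
  stopifnot(inherits(ratio, "variance_ratio"))
  target_type <- match.arg(target_type)
  # go through alpha = within/between
  alpha <- switch(ratio$type,
    within_between = ratio$value,
    within_total = ratio$value / (1 - ratio$value),
    between_total = (1 - ratio$value) / ratio$value)
  value <- switch(target_type,
    within_between = alpha,
    within_total = alpha / (1 + alpha),
    between_total = 1 / (1 + alpha))
  variance_ratio(value, target_type)
}

#' Split a total variance into between- and within-person components
#'
#' Given the total residual variance \eqn{V} of a single-recall model and
#' an external variance ratio, returns the implied components:
#' \tabular{lll}{
#'   ratio type \tab between \tab within \cr
#'   \eqn{\alpha} (within:between) \tab \eqn{V/(1+\alpha)} \tab
#'     \eqn{V\alpha/(1+\alpha)} \cr
#'   \eqn{\beta} (within:total) \tab \eqn{V(1-\beta)} \tab \eqn{V\beta} \cr
#'   \eqn{\gamma} (between:total) \tab \eqn{V\gamma} \tab \eqn{V(1-\gamma)}
#' }
#' The two components always sum to \eqn{V}.
#'
#' @param V total variance (>= 0), transformed scale.
#' @param ratio a [variance_ratio()].
#' @return named numeric vector \code{c(var_between, var_within)}.
#' @examples
#' split_variance(20, variance_ratio(2, "within_between"))
#' # between 6.67, within 13.3
#' @export
split_variance <- function(V, ratio) {
  stopifnot(inherits(ratio, "variance_ratio"))
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V) || V < 0) {
    stop_config("total variance V must be a single nonnegative number")
  }
  out <- switch(ratio$type,
    within_between = c(V / (1 + ratio$value),
                       V * ratio$value / (1 + ratio$value)),
    within_total = c(V * (1 - ratio$value), V * ratio$value),
    between_total = c(V * ratio$value, V * (1 - ratio$value)))
  names(out) <- c("var_between", "var_within")
  out
}
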