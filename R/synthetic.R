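#' Specification for the synthetic recall-data generator
#'
#' Describes a data-generating process of the same form as the
#' amount-only model: on the Box-Cox transformed scale a person-day
#' intake is
#' \deqn{\beta_0 + \beta_{age} Age_i + \beta_{g(i)} + \beta_{we} W_{ij}
#'       + u_i + e_{ij}}
#' with normal person effects and day-to-day errors, then back-transformed
#' to the intake scale (negative back-transform arguments clip to zero,
#' counted against the nearly-daily budget of 5\% zeros).
#'
#' Defaults emulate a single micronutrient analysed in adult men: a
#' transformed-scale intercept placed so intakes land in the hundreds of
#' units/day at \eqn{\lambda = 0.25}, a continuous age effect, a 3-level
#' race/ethnicity-style group with unequal proportions, a weekend
#' indicator with probability 3/7, variance components
#' \eqn{\sigma^2_u = 0.5}, \eqn{\sigma^2_e = 1.0} (within:between ratio
#' 2), and gamma-distributed survey weights with mean 1.
#'
#' @param n_persons number of persons.
#' @param days_per_person recalls per person (1 for the one-day design,
#'   2+ for replicate designs).
#' @param lambda true Box-Cox parameter.
#' @param beta0 transformed-scale intercept.
#' @param beta_age age slope (per year, transformed scale).
#' @param beta_group group effects (first is the reference, must be 0).
#' @param beta_weekend weekend effect.
#' @param sigma2_u,sigma2_e between- and within-person variances.
#' @param age_range uniform age range in years.
#' @param group_prob group membership probabilities.
#' @param p_weekend probability a recall day is a weekend day.
#' @param weight_scheme \code{"gamma"} (shape 4, mean 1) or
#'   \code{"equal"}.
#' @param n_replicates number of BRR replicate-weight columns to attach
#'   (0 for none; power of two).
#' @param fay Fay coefficient for the replicate weights.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return list of class \code{generator_spec}.
#' @export
generator_spec <- function(n_persons = 5000, days_per_person = 2,
                           lambda = 0.25, beta0 = 15,
                           beta_age = 0.02, beta_group = c(0, -0.5, 0.3),
                           beta_weekend = 0.3,
                           sigma2_u = 0.5, sigma2_e = 1.0,
                           age_range = c(19, 80),
                           group_prob = c(0.4, 0.3, 0.3),
                           p_weekend = 3 / 7,
                           weight_scheme = c("gamma", "equal"),
                           n_replicates = 0, fay = 0, seed = 1) {
  weight_scheme <- match.arg(weight_scheme)
  if (sigma2_u < 0 || sigma2_e < 0) stop_config("variances must be nonnegative")
  if (p_weekend < 0 || p_weekend > 1) stop_config("p_weekend must lie in [0, 1]")
  if (abs(sum(group_prob) - 1) > 1e-8 || any(group_prob < 0)) {
    stop_config("group probabilities must be nonnegative and sum to 1")
  }
  if (beta_group[1] != 0) stop_config("first group effect is the reference and must be 0")
  structure(list(n_persons = n_persons, days_per_person = days_per_person,
                 lambda = lambda, beta0 = beta0, beta_age = beta_age,
                 beta_group = beta_group, beta_weekend = beta_weekend,
                 sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 age_range = age_range, group_prob = group_prob,
                 p_weekend = p_weekend, weight_scheme = weight_scheme,
                 n_replicates = n_replicates, fay = fay, seed = seed),
            class = "generator_spec")
}

#' Generate a synthetic recall table with known truth
#'
#' Simulates person-day 24-hour recall records from a [generator_spec()]
#' and returns, alongside the recall table, a per-person truth table:
#' the drawn person effect and the closed-form true usual intake (the
#' within-person error integrated out by high-order quadrature with the
#' generator's own parameters, day types mixed with weights
#' \code{(1 - p_weekend, p_weekend)}, which at the default
#' \code{p_weekend = 3/7} matches the 4/7 : 3/7 weekday/weekend mix).
#' Errors if the generated data violate the
#' nearly-daily criterion (>= 5\% zero intakes after clipping).
#'
#' @param spec a [generator_spec()].
#' @return list with elements \code{recalls} (data frame: person_id, day,
#'   age, group, weekend, intake, weight, optional repwt_* columns) and
#'   \code{truth} (data frame: person_id, weight, u, lp_weekday,
#'   lp_weekend, usual_intake).
#' @examples
#' g <- generate_recalls(generator_spec(n_persons = 100, seed = 3))
#' head(g$recalls); head(g$truth)
#' @export
generate_recalls <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_persons
    J <- spec$days_per_person
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    group <- factor(sample(seq_along(spec$group_prob), n, replace = TRUE,
                           prob = spec$group_prob),
                    levels = seq_along(spec$group_prob),
                    labels = paste0("g", seq_along(spec$group_prob)))
    u <- stats::rnorm(n, 0, sqrt(spec$sigma2_u))
    w <- switch(spec$weight_scheme,
                equal = rep(1, n),
                gamma = stats::rgamma(n, shape = 4, rate = 4))
    lp_person <- spec$beta0 + spec$beta_age * age +
      spec$beta_group[as.integer(group)]

    idx <- rep(seq_len(n), each = J)
    weekend <- stats::rbinom(n * J, 1, spec$p_weekend)
    e <- stats::rnorm(n * J, 0, sqrt(spec$sigma2_e))
    z <- lp_person[idx] + spec$beta_weekend * weekend + u[idx] + e
    intake <- bc_inverse(z, spec$lambda)
    frac_zero <- mean(as.numeric(intake) == 0)
    if (frac_zero >= 0.05) {
      stop_data(sprintf(
        "spec generates %.1f%% zero intakes, violating the nearly-daily criterion (< 5%%)",
        100 * frac_zero))
    }
    recalls <- data.frame(person_id = idx,
                          day = rep(seq_len(J), times = n),
                          age = age[idx], group = group[idx],
                          weekend = weekend,
                          intake = as.numeric(intake),
                          weight = w[idx])
    if (spec$n_replicates > 0) {
      recalls <- make_replicate_weights(recalls, n_sets = spec$n_replicates,
                                        fay = spec$fay)
    }
    # closed-form truth: within-person error integrated out at high order
    daytype <- day_type_weights(weekday = 1 - spec$p_weekend,
                                weekend = spec$p_weekend)
    truth_ui <- usual_intake_of_person(lp_person, lp_person + spec$beta_weekend,
                                       u, lambda = spec$lambda,
                                       sigma2_e = spec$sigma2_e,
                                       daytype = daytype, nodes = 41)
    truth <- data.frame(person_id = seq_len(n), weight = w, u = u,
                        lp_weekday = lp_person,
                        lp_weekend = lp_person + spec$beta_weekend,
                        usual_intake = as.numeric(truth_ui))
    list(recalls = recalls, truth = truth)
  })
}

#' Attach BRR replicate weights to a recall table
#'
#' Builds classical (or Fay-adjusted) balanced-repeated-replication
#' replicate weights: persons are paired into variance strata in id
#' order, and each replicate doubles one member of each pair and zeroes
#' the other (factors \eqn{2-F} and \eqn{F} under Fay's method) following
#' a Sylvester Hadamard design. \code{n_sets} must be a power of two
#' (the common 32-replicate NHANES-style setup is covered).
#'
#' @param table recall data frame with \code{person_id} and \code{weight}
#'   columns.
#' @param n_sets number of replicate-weight sets (power of two).
#' @param fay Fay coefficient in \[0, 1).
#' @param prefix column-name prefix for the new weight columns.
#' @return the table with \code{n_sets} added columns
#'   \code{<prefix>1 .. <prefix>n_sets}.
#' @export
make_replicate_weights <- function(table, n_sets = 32, fay = 0,
                                   prefix = "repwt_") {
  if (n_sets < 1 || bitwAnd(n_sets, n_sets - 1L) != 0) {
    stop_config("n_sets must be a power of two (Sylvester Hadamard construction)")
  }
  if (fay < 0 || fay >= 1) stop_config("Fay coefficient must lie in [0, 1)")
  ids <- unique(table$person_id)
  n <- length(ids)
  if (n %% 2 != 0) stop_data("BRR pairing needs an even number of persons")
  # Sylvester Hadamard matrix of order n_sets
  H <- matrix(1, 1, 1)
  while (nrow(H) < n_sets) H <- rbind(cbind(H, H), cbind(H, -H))
  n_strata <- n / 2
  stratum <- rep(seq_len(n_strata), each = 2)      # pairs in id order
  member <- rep(c(1L, -1L), times = n_strata)
  col_of <- ((seq_len(n_strata) - 1L) %% n_sets) + 1L
  pos <- match(table$person_id, ids)
  for (r in seq_len(n_sets)) {
    sign_p <- H[r, col_of[stratum]] * member       # +1 -> doubled member
    fac <- ifelse(sign_p > 0, 2 - fay, fay)
    table[[paste0(prefix, r)]] <- table$weight * fac[pos]
  }
  table
}
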