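# Prior distributions for the Q-model parameters.
#
# Generic kinetic parameters get wide uniform priors (+/-100 % of their
# literature values), local parameters get truncated normals centred on
# literature values with a 10 % coefficient of variation.

#' Prior specification for the Q-model calibration
#'
#' Default priors: `eta11 ~ Uniform(0, 0.72)` and `u0 ~ Uniform(0, 0.98)`
#' (twice the literature values 0.36 and 0.5 x 0.98, the latter with the
#' decomposer carbon concentration absorbed into `u0`);
#' `beta0 ~ Normal(0.7, sd 0.07)` truncated to +/-33 % of 0.7
#' (`[0.469, 0.931]`); `q0 ~ Normal(1.08, sd 0.108)` truncated to
#' `[0.5, 1.5]`; `e0 ~ Normal(0.3, sd 0.03)` truncated to `[0, 0.6]`.
#' `q0`, `e0` and `beta0` are site-local, `u0` and `eta11` generic.
#'
#' @param eta11_upper,u0_upper Upper bounds of the uniform priors.
#' @param beta0_mean,beta0_cv,beta0_trunc Mean, coefficient of variation and
#'   relative truncation half-width of the `beta0` prior.
#' @param q0_mean,q0_cv,q0_bounds Centre, coefficient of variation and
#'   truncation bounds of the `q0` prior.
#' @param e0_mean,e0_cv,e0_bounds Centre, coefficient of variation and
#'   truncation bounds of the `e0` prior.
#' @return A tibble of class `qm_priors` with columns `parameter`, `scope`
#'   (`"generic"` or `"local"`), `dist` (`"uniform"` or `"tnorm"`), `mean`,
#'   `sd`, `lower`, `upper`.
#' @examples
#' qm_priors()
#' @export
qm_priors <- function(eta11_upper = 2 * 0.36, u0_upper = 2 * 0.5 * 0.98,
                      beta0_mean = 0.7, beta0_cv = 0.1, beta0_trunc = 0.33,
                      q0_mean = 1.08, q0_cv = 0.1, q0_bounds = c(0.5, 1.5),
                      e0_mean = 0.3, e0_cv = 0.1, e0_bounds = c(0, 0.6)) {
  pr <- tibble::tibble(
    parameter = c("u0", "eta11", "q0", "e0", "beta0"),
    scope = c("generic", "generic", "local", "local", "local"),
    dist = c("uniform", "uniform", "tnorm", "tnorm", "tnorm"),
    mean = c(NA, NA, q0_mean, e0_mean, beta0_mean),
    sd = c(NA, NA, q0_mean * q0_cv, e0_mean * e0_cv, beta0_mean * beta0_cv),
    lower = c(0, 0, q0_bounds[1], e0_bounds[1],
              beta0_mean * (1 - beta0_trunc)),
    upper = c(u0_upper, eta11_upper, q0_bounds[2], e0_bounds[2],
              beta0_mean * (1 + beta0_trunc))
  )
  stopifnot(all(pr$lower < pr$upper), all(is.finite(pr$lower)),
            all(is.finite(pr$upper)))
  class(pr) <- c("qm_priors", class(pr))
  pr
}

#' Log prior density of one parameter
#'
#' Evaluates the (normalized) log density of `value` under the prior row for
#' `parameter`. Values outside the truncation bounds give `-Inf`.
#'
#' @param value Numeric vector of parameter values.
#' @param parameter Parameter name (one of the rows of `priors`).
#' @param priors A [qm_priors()] tibble.
#' @return Log density vector.
#' @export
log_prior_density <- function(value, parameter, priors = qm_priors()) {
  row <- priors[priors$parameter == parameter, ]
  if (nrow(row) != 1) stop("unknown parameter: ", parameter, call. = FALSE)
  out <- rep(-Inf, length(value))
  inside <- value >= row$lower & value <= row$upper
  if (row$dist == "uniform") {
    out[inside] <- -log(row$upper - row$lower)
  } else {
    z <- pnorm_range(row$mean, row$sd, row$lower, row$upper)
    out[inside] <- dnorm(value[inside], row$mean, row$sd, log = TRUE) - log(z)
  }
  out
}

#' Draw from a prior marginal
#'
#' Inverse-CDF sampling from the prior of one parameter (exact for both the
#' uniform and the truncated-normal families).
#'
#' @inheritParams log_prior_density
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_prior <- function(n, parameter, priors = qm_priors()) {
  row <- priors[priors$parameter == parameter, ]
  if (nrow(row) != 1) stop("unknown parameter: ", parameter, call. = FALSE)
  u <- runif(n)
  if (row$dist == "uniform") {
    row$lower + u * (row$upper - row$lower)
  } else {
    plo <- stats::pnorm(row$lower, row$mean, row$sd)
    phi <- stats::pnorm(row$upper, row$mean, row$sd)
    qnorm(plo + u * (phi - plo), row$mean, row$sd)
  }
}

pnorm_range <- function(mean, sd, lower, upper) {
  stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
}

# internal: typical scale of each prior, used to seed proposal step sizes
prior_scale <- function(row) {
  if (row$dist == "uniform") (row$upper - row$lower) / sqrt(12) else row$sd
}
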