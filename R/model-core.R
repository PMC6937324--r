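# Closed-form continuous-quality (Q) kinetics for SOC decay under zero input.
#
# The model tracks the stock-average quality qbar of soil organic matter: each
# unit of carbon carries a dimensionless quality inversely related to its
# persistence, and reprocessing by decomposers pushes the average quality down.
# With inputs stopped (bare fallow) both the stock and the plant-derived pool
# admit closed forms, so no numerical integration is needed anywhere in the
# forward model.

#' Effective edaphic shape parameter
#'
#' Combines the calibrated edaphic offset `beta0` with the measured clay
#' concentration of the soil. Clay enters additively at 0.01 per percent,
#' so a clay-rich soil steepens the quality dependence of decomposer growth.
#'
#' @param beta0 Calibrated edaphic offset (dimensionless, > 0).
#' @param clay_percent Clay concentration of the soil in percent (0--100).
#' @return The effective shape parameter `beta0 + 0.01 * clay_percent`.
#' @examples
#' effective_beta(0.7, 36)
#' @export
effective_beta <- function(beta0, clay_percent) {
  check_num(beta0, "beta0", lower = 0, strict = TRUE)
  check_num(clay_percent, "clay_percent", lower = 0, upper = 100)
  beta0 + 0.01 * clay_percent
}

#' Mean quality of soil organic matter at time t
#'
#' Average SOM quality under zero input. Quality decreases monotonically from
#' the initial litter quality `q0` towards zero as the material is reprocessed;
#' the decline is governed by the product of the quality-shift rate `eta11`,
#' the climate-scaled decomposer metabolic rate `u0 * re`, and the shape
#' parameter `beta`.
#'
#' For `beta` below `beta_tol` the closed form degenerates ( `(1 + b x)^(1/b)` )
#' and the exponential limit `q0 * exp(-eta11 * u0 * re * q0^beta * t)` is used
#' instead.
#'
#' @param t Time in years since the start of the experiment (>= 0).
#' @param q0 Initial litter quality (dimensionless, > 0).
#' @param beta Effective edaphic shape parameter (see [effective_beta()]).
#' @param eta11 Rate of decrease in quality (dimensionless, > 0).
#' @param u0 Decomposer metabolic rate (per year on the quality scale, > 0).
#' @param re Normalized climate scalar (dimensionless, > 0); defaults to 1,
#'   i.e. the cross-site average climate.
#' @param beta_tol Threshold below which the exponential beta -> 0 limit is
#'   used. Default `1e-8`.
#' @return Mean quality, in `(0, q0]`.
#' @examples
#' mean_quality(10, q0 = 1.08, beta = 0.87, eta11 = 0.36, u0 = 0.49)
#' @export
mean_quality <- function(t, q0, beta, eta11, u0, re = 1, beta_tol = 1e-8) {
  check_num(t, "t", lower = 0)
  check_num(q0, "q0", lower = 0, strict = TRUE)
  check_num(beta, "beta", lower = 0, strict = TRUE)
  check_num(eta11, "eta11", lower = 0, strict = TRUE)
  check_num(u0, "u0", lower = 0, strict = TRUE)
  check_num(re, "re", lower = 0, strict = TRUE)
  a <- eta11 * u0 * re * q0^beta * t
  out <- q0 * exp(-log1p(beta * a) / beta)
  small <- rep_len(beta < beta_tol, length(out))
  if (any(small)) {
    out[small] <- rep_len(q0 * exp(-a), length(out))[small]
  }
  out
}

#' Exponent linking quality decline to stock decline
#'
#' The bracketed exponent of the stock equation, `(1 - e0) / (eta11 * e0) -
#' beta`. A valid parameter set must give a strictly positive exponent;
#' otherwise the stock would not decay as quality declines.
#'
#' @param e0 Decomposer efficiency (carbon use efficiency), in (0, 1).
#' @param eta11 Rate of decrease in quality (> 0).
#' @param beta Effective edaphic shape parameter.
#' @return The dimensionless exponent.
#' @examples
#' decay_exponent(0.3, 0.36, 0.87)
#' @export
decay_exponent <- function(e0, eta11, beta) {
  check_num(e0, "e0", lower = 0, upper = 1, strict = TRUE)
  check_num(eta11, "eta11", lower = 0, strict = TRUE)
  (1 - e0) / (eta11 * e0) - beta
}

#' SOC stock at time t under bare fallow
#'
#' Stock of soil organic carbon after `t` years without input, starting from
#' the steady-state stock `css`. The stock follows the mean quality:
#' `css * (mean_quality(t) / q0) ^ decay_exponent`. There is no inert floor:
#' the stock decreases strictly towards zero but stays positive at every
#' finite time.
#'
#' @inheritParams mean_quality
#' @param css SOC stock at steady state, i.e. at the start of the experiment
#'   (Mg C ha^-1, > 0).
#' @param e0 Decomposer efficiency, in (0, 1).
#' @return SOC stock in the units of `css`.
#' @examples
#' soc_stock(10, css = 65.5, q0 = 1.08, beta = 0.87, eta11 = 0.36,
#'           u0 = 0.05, e0 = 0.3)
#' @export
soc_stock <- function(t, css, q0, beta, eta11, u0, e0, re = 1,
                      beta_tol = 1e-8) {
  check_num(css, "css", lower = 0, strict = TRUE)
  expnt <- decay_exponent(e0, eta11, beta)
  if (any(expnt <= 0)) {
    stop("invalid parameter set: decay exponent (1 - e0)/(eta11 * e0) - beta ",
         "must be positive (got ", paste(signif(expnt, 4), collapse = ", "),
         ")", call. = FALSE)
  }
  qbar <- mean_quality(t, q0, beta, eta11, u0, re, beta_tol)
  css * (qbar / q0)^expnt
}

#' Initial SOM quality at equilibrium
#'
#' Average quality of the SOM pool at equilibrium with the pre-experiment
#' inputs, as a linear function of the litter input quality `q0`. Always below
#' `q0` whenever `eta11 * e0 > 0`, since the resident material has already
#' been partially reprocessed.
#'
#' @inheritParams decay_exponent
#' @param q0 Initial litter quality (> 0).
#' @return Equilibrium mean SOM quality (dimensionless).
#' @examples
#' initial_som_quality(1.08, 0.3, 0.36, 0.87)
#' @export
initial_som_quality <- function(q0, e0, eta11, beta) {
  check_num(q0, "q0", lower = 0, strict = TRUE)
  check_num(e0, "e0", lower = 0, upper = 1, strict = TRUE)
  # eta11 = 0 is admitted here: the ratio collapses to 1 and the
  # equilibrium quality equals the litter quality
  check_num(eta11, "eta11", lower = 0)
  num <- 1 - e0 - eta11 * e0 * beta
  den <- 1 - e0 - eta11 * e0 * (beta - 1)
  if (any(num <= 0)) {
    stop("invalid parameter set: 1 - e0 - eta11 * e0 * beta must be positive",
         call. = FALSE)
  }
  q0 * num / den
}

#' Steady-state plant-derived pool
#'
#' Size of the pool of plant-derived material (material still at quality `q0`)
#' at steady state under a constant input rate `input`. Linear in the input.
#'
#' @param input Carbon input rate (mass per year, >= 0).
#' @param e0 Decomposer efficiency, in (0, 1).
#' @param u0 Decomposer metabolic rate (> 0).
#' @param q0 Initial litter quality (> 0).
#' @param beta Effective edaphic shape parameter.
#' @return Pool size `e0 * input / (u0 * q0^beta)`, in the units of
#'   `input` times years.
#' @export
steady_state_plant_pool <- function(input, e0, u0, q0, beta) {
  check_num(input, "input", lower = 0)
  check_num(u0, "u0", lower = 0, strict = TRUE)
  check_num(q0, "q0", lower = 0, strict = TRUE)
  e0 * input / (u0 * q0^beta)
}

#' Fraction of plant-derived material remaining
#'
#' Exponential decay of the plant-derived pool (normalized to 1 at `t = 0`)
#' once inputs stop. The climate scalar `re` rescales the metabolic rate
#' wherever `u0` appears.
#'
#' Two published renderings of the decay exponent are in circulation and are
#' reciprocals of each other. The default, `"decay_rate"`, uses
#' `k = u0 * re * q0^beta / e0` -- the rate constant of the plant-pool mass
#' balance, dimensionally a decomposition rate. `"reciprocal"` uses
#' `k = e0 / (u0 * re * q0^beta)` as typeset in one published formulation;
#' it is provided for comparison.
#'
#' @inheritParams mean_quality
#' @param e0 Decomposer efficiency, in (0, 1).
#' @param rate_convention Either `"decay_rate"` (default) or `"reciprocal"`.
#' @return Fraction remaining, in (0, 1].
#' @examples
#' plant_fraction(10, q0 = 1.08, beta = 0.87, e0 = 0.3, u0 = 0.05)
#' @export
plant_fraction <- function(t, q0, beta, e0, u0, re = 1,
                           rate_convention = c("decay_rate", "reciprocal")) {
  rate_convention <- match.arg(rate_convention)
  check_num(t, "t", lower = 0)
  check_num(q0, "q0", lower = 0, strict = TRUE)
  check_num(e0, "e0", lower = 0, upper = 1, strict = TRUE)
  check_num(u0, "u0", lower = 0, strict = TRUE)
  check_num(re, "re", lower = 0, strict = TRUE)
  k <- if (rate_convention == "decay_rate") {
    u0 * re * q0^beta / e0
  } else {
    e0 / (u0 * re * q0^beta)
  }
  exp(-k * t)
}

#' Validate a full Q-model parameter set
#'
#' Checks every structural validity rule of the model: positivity of all
#' parameters, efficiency within (0, 1), a positive decay exponent, and a
#' positive equilibrium-quality numerator `1 - e0 - eta11 * e0 * beta`.
#' Returns a verdict per parameter set rather than raising, so the sampler
#' and user code can treat invalid proposals as zero-probability.
#'
#' Local parameters (`q0`, `e0`, `beta0`, `clay_percent`) may be vectors (one
#' element per site); `u0` and `eta11` are the shared generic kinetics and are
#' recycled.
#'
#' @param u0,eta11 Generic kinetic parameters.
#' @param q0,e0,beta0 Site-local parameters.
#' @param clay_percent Clay concentration per site (percent); default 0.
#' @return A tibble with one row per parameter set: the parameter values,
#'   `valid` (logical) and `violations` (list column of character vectors,
#'   empty when valid).
#' @examples
#' validate_parameters(u0 = 0.49, eta11 = 0.36, q0 = 1.08, e0 = 0.3,
#'                     beta0 = 0.7, clay_percent = 17)
#' @export
validate_parameters <- function(u0, eta11, q0, e0, beta0, clay_percent = 0) {
  n <- max(lengths(list(u0, eta11, q0, e0, beta0, clay_percent)))
  u0 <- rep_len(u0, n); eta11 <- rep_len(eta11, n)
  q0 <- rep_len(q0, n); e0 <- rep_len(e0, n)
  beta0 <- rep_len(beta0, n); clay_percent <- rep_len(clay_percent, n)

  violations <- purrr::pmap(
    list(u0, eta11, q0, e0, beta0, clay_percent),
    function(u0, eta11, q0, e0, beta0, clay) {
      v <- character()
      if (!is.finite(u0) || u0 <= 0) v <- c(v, "positivity: u0 > 0")
      if (!is.finite(eta11) || eta11 <= 0) v <- c(v, "positivity: eta11 > 0")
      if (!is.finite(q0) || q0 <= 0) v <- c(v, "positivity: q0 > 0")
      if (!is.finite(e0) || e0 <= 0 || e0 >= 1) v <- c(v, "range: 0 < e0 < 1")
      if (!is.finite(beta0) || beta0 <= 0) v <- c(v, "positivity: beta0 > 0")
      if (!is.finite(clay) || clay < 0 || clay > 100) {
        v <- c(v, "range: 0 <= clay <= 100")
      }
      if (length(v) == 0) {
        beta <- beta0 + 0.01 * clay
        if ((1 - e0) / (eta11 * e0) - beta <= 0) {
          v <- c(v, "decay exponent: (1 - e0)/(eta11 * e0) - beta > 0")
        }
        if (1 - e0 - eta11 * e0 * beta <= 0) {
          v <- c(v, "equilibrium quality: 1 - e0 - eta11 * e0 * beta > 0")
        }
      }
      v
    }
  )
  tibble::tibble(
    u0 = u0, eta11 = eta11, q0 = q0, e0 = e0, beta0 = beta0,
    clay_percent = clay_percent,
    valid = lengths(violations) == 0,
    violations = violations
  )
}

# internal: domain check for numeric arguments; strict = open interval
check_num <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x)) stop(name, " must be numeric", call. = FALSE)
  bad <- if (strict) {
    any(!is.finite(x) | x <= lower | x >= upper)
  } else {
    any(!is.finite(x) | x < lower | x > upper)
  }
  if (bad) {
    stop(name, " must be finite and ",
         if (strict) paste0("strictly inside (", lower, ", ", upper, ")")
         else paste0("in [", lower, ", ", upper, "]"),
         call. = FALSE)
  }
  invisible(x)
}
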