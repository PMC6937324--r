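# Hierarchical Bayesian calibration of the Q model on multi-site
# bare-fallow data.
#
# Generic kinetics (u0, eta11) are shared across sites and updated against
# the pooled likelihood; local parameters (q0, e0, beta0) are per site and
# updated against their own site's likelihood. Stock and plant-fraction
# series are calibrated simultaneously under independent Gaussian error
# models whose standard deviations are the average replicate SD of each
# series.

#' Gaussian log likelihood of a parameter set
#'
#' Sum over sites and over both observables (SOC stock and, when present,
#' plant-derived fraction) of independent Gaussian log densities. The error
#' standard deviation of each series is its average replicate SD. Invalid
#' parameter sets return `-Inf` rather than raising, so samplers can treat
#' them as rejected.
#'
#' This is the reference implementation used for testing; [run_mcmc()]
#' evaluates an equivalent compiled version internally.
#'
#' @param params A parameter list: `u0`, `eta11` (scalars) and `locals`, a
#'   data frame with columns `site_id`, `q0`, `e0`, `beta0`.
#' @param data A [qm_data()] object.
#' @param annualize Interpolate observations to annual resolution first
#'   (default `TRUE`, mirroring how the irregular archives are calibrated).
#' @param rate_convention Passed to [plant_fraction()].
#' @param pf_sd_default Plant-fraction error SD used when the series carries
#'   none. Default 0.1 (10 % of the initial fraction).
#' @return The log likelihood (scalar; `-Inf` for invalid parameters).
#' @export
log_likelihood <- function(params, data, annualize = TRUE,
                           rate_convention = "decay_rate",
                           pf_sd_default = 0.1) {
  prep <- prepare_sites(data, annualize, pf_sd_default)
  ll <- 0
  for (s in prep) {
    loc <- params$locals[params$locals$site_id == s$site_id, ]
    v <- validate_parameters(params$u0, params$eta11, loc$q0, loc$e0,
                             loc$beta0, s$clay)
    if (!v$valid) return(-Inf)
    beta <- effective_beta(loc$beta0, s$clay)
    pred <- soc_stock(s$t_soc, s$css, loc$q0, beta, params$eta11,
                      params$u0, loc$e0, s$re)
    ll <- ll + sum(dnorm(s$y_soc, pred, s$sd_soc, log = TRUE))
    if (length(s$t_pf) > 0) {
      pf <- plant_fraction(s$t_pf, loc$q0, beta, loc$e0, params$u0, s$re,
                           rate_convention)
      ll <- ll + sum(dnorm(s$y_pf, pf, s$sd_pf, log = TRUE))
    }
  }
  ll
}

#' Root-mean-square error of the SOC fit at one site
#'
#' RMSE of the SOC-stock residuals over the site's (annualized) series, in
#' Mg C ha^-1.
#'
#' @inheritParams log_likelihood
#' @param site_id Site to evaluate.
#' @return RMSE (Mg C ha^-1).
#' @export
rmse_site <- function(params, data, site_id, annualize = TRUE) {
  prep <- prepare_sites(data, annualize, 0.1)
  s <- purrr::detect(prep, ~ .x$site_id == site_id)
  if (is.null(s)) stop("unknown site: ", site_id, call. = FALSE)
  if (length(s$t_soc) == 0) stop("empty series for site ", site_id,
                                 call. = FALSE)
  loc <- params$locals[params$locals$site_id == site_id, ]
  beta <- effective_beta(loc$beta0, s$clay)
  pred <- soc_stock(s$t_soc, s$css, loc$q0, beta, params$eta11, params$u0,
                    loc$e0, s$re)
  sqrt(mean((s$y_soc - pred)^2))
}

#' Calibrate the Q model by blocked adaptive Metropolis-Hastings
#'
#' Samples the posterior of the hierarchical Q-model calibration: generic
#' kinetics `u0` and `eta11` shared across sites, local `q0`, `e0`, `beta0`
#' per site (or shared too, under `parameterization = "generic"`). Proposals
#' are Gaussian random walks in blocks (the generic pair jointly against the
#' pooled likelihood; each site's locals jointly against their own site),
#' plus one joint move over the full parameter vector per iteration to
#' traverse correlations that cross blocks. Proposal covariances and scales
#' adapt (adaptive-Metropolis style) during burn-in only. Every chain records the full parameter set, log prior, log
#' likelihood, log posterior and per-site SOC RMSE at each kept iteration.
#'
#' @param data A [qm_data()] object.
#' @param priors A [qm_priors()] specification.
#' @param n_chains Number of independent chains. Default 4.
#' @param n_iter Iterations per chain. Default 100000.
#' @param burn_in Iterations treated as burn-in (adaptation window and
#'   excluded from all posterior summaries). Default 10000.
#' @param thin Keep every `thin`-th iteration. Default 1.
#' @param seed Integer seed; identical seeds give identical chains.
#' @param parameterization `"local"` (default; per-site locals) or
#'   `"generic"` (one shared set of `q0`, `e0`, `beta0` for all sites, used
#'   for the first-stage sensitivity screening).
#' @param rate_convention Plant-fraction rate convention (see
#'   [plant_fraction()]).
#' @param annualize Interpolate observations to annual resolution before
#'   calibrating (default `TRUE`); set `FALSE` to use the raw observation
#'   times only.
#' @param flat_likelihood If `TRUE`, replace the likelihood by a constant so
#'   the sampler targets the prior (validity rules still apply); used to
#'   verify prior recovery.
#' @param target_accept Target acceptance rate of the adaptive scaling.
#'   Default 0.3.
#' @param pf_sd_default Plant-fraction error SD when the series carries none.
#' @return An object of class `qm_fit`: a list with `draws` (tibble: `chain`,
#'   `iteration`, one column per parameter -- local parameters suffixed by
#'   site id -- `log_prior`, `log_lik`, `log_post`, and `rmse_<site>`
#'   columns), `accept` (per-chain, per-block acceptance rates), `data`,
#'   `priors` and `config`.
#' @examples
#' d <- simulate_ltbf(n_sites = 2, seed = 1, n_obs = 6)
#' fit <- run_mcmc(d, n_chains = 2, n_iter = 2000, burn_in = 500, seed = 1)
#' tidy(fit)
#' @export
run_mcmc <- function(data, priors = qm_priors(), n_chains = 4,
                     n_iter = 100000, burn_in = 10000, thin = 1, seed = 1,
                     parameterization = c("local", "generic"),
                     rate_convention = c("decay_rate", "reciprocal"),
                     annualize = TRUE, flat_likelihood = FALSE,
                     target_accept = 0.3, pf_sd_default = 0.1) {
  parameterization <- match.arg(parameterization)
  rate_convention <- match.arg(rate_convention)
  stopifnot(n_chains >= 1, n_iter >= 1, burn_in >= 0, burn_in < n_iter,
            thin >= 1)
  prep <- prepare_sites(data, annualize, pf_sd_default)
  if (length(prep) < 1) stop("need at least one site", call. = FALSE)
  site_ids <- vapply(prep, `[[`, "", "site_id")

  layout <- param_layout(site_ids, parameterization)
  prior_spec <- build_prior_spec(layout, priors)

  site_list <- lapply(prep, function(s) {
    list(t_soc = s$t_soc, y_soc = s$y_soc, sd_soc = s$sd_soc,
         t_pf = s$t_pf, y_pf = s$y_pf, sd_pf = s$sd_pf,
         css = s$css, clay = s$clay, re = s$re)
  })

  config <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), target_accept = target_accept,
                 flat = flat_likelihood,
                 conv = if (rate_convention == "decay_rate") 0L else 1L,
                 adapt_interval = 100L)

  chains <- vector("list", n_chains)
  accept <- vector("list", n_chains)
  set.seed(seed)
  for (ch in seq_len(n_chains)) {
    init <- draw_valid_init(layout, priors, prep)
    res <- qm_run_chain(init, layout$blocks0, layout$block_site0, prior_spec,
                        layout$local_idx0, site_list, config)
    draws <- tibble::as_tibble(as.data.frame(res$draws))
    names(draws) <- layout$par_names
    rmse <- tibble::as_tibble(as.data.frame(res$rmse))
    names(rmse) <- paste0("rmse_", site_ids)
    chains[[ch]] <- dplyr::bind_cols(
      tibble::tibble(chain = ch, iteration = res$iteration),
      draws,
      tibble::tibble(log_prior = res$log_prior, log_lik = res$log_lik,
                     log_post = res$log_post),
      rmse
    )
    accept[[ch]] <- tibble::tibble(
      chain = ch,
      block = layout$block_names,
      accept_rate = as.numeric(res$accept_rate),
      accept_rate_post_burnin = as.numeric(res$accept_rate_post)
    )
  }

  structure(
    list(
      draws = dplyr::bind_rows(chains),
      accept = dplyr::bind_rows(accept),
      data = data,
      priors = priors,
      site_ids = site_ids,
      par_names = layout$par_names,
      parameterization = parameterization,
      config = c(config, list(n_chains = n_chains, seed = seed,
                              annualize = annualize,
                              rate_convention = rate_convention))
    ),
    class = "qm_fit"
  )
}

#' Post-burn-in draws of a fit
#'
#' @param fit A `qm_fit` object.
#' @return The draws tibble restricted to iterations after the burn-in.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "qm_fit"))
  dplyr::filter(fit$draws, .data$iteration > fit$config$burn_in)
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Classic between-/within-chain variance ratio computed on post-burn-in
#' draws: with `m` chains of length `n`, `W` the mean within-chain variance
#' and `B/n` the variance of the chain means, the statistic is
#' `sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate mixing; the
#' conventional good-mixing threshold is 1.1.
#'
#' @param x A `qm_fit` object, or a draws tibble with a `chain` column.
#' @param pars Parameter columns to monitor; defaults to all model
#'   parameters (for a fit) or all non-bookkeeping numeric columns.
#' @return A tibble with columns `parameter`, `rhat`.
#' @export
gelman_rubin <- function(x, pars = NULL) {
  draws <- if (inherits(x, "qm_fit")) {
    if (is.null(pars)) pars <- x$par_names
    posterior_draws(x)
  } else {
    if (is.null(pars)) {
      pars <- setdiff(names(x)[vapply(x, is.numeric, TRUE)],
                      c("chain", "iteration", "log_prior", "log_lik",
                        "log_post"))
      pars <- pars[!startsWith(pars, "rmse_")]
    }
    x
  }
  if (length(unique(draws$chain)) < 2) {
    stop("gelman_rubin needs at least 2 chains", call. = FALSE)
  }
  n_len <- min(table(draws$chain))
  if (n_len < 10) stop("chains too short for gelman_rubin", call. = FALSE)
  purrr::map_dfr(pars, function(p) {
    by_chain <- split(draws[[p]], draws$chain)
    m <- length(by_chain)
    n <- min(lengths(by_chain))
    by_chain <- lapply(by_chain, function(v) v[seq_len(n)])
    means <- vapply(by_chain, mean, 0)
    vars <- vapply(by_chain, var, 0)
    w <- mean(vars)
    b_over_n <- var(means) # = B/n
    rhat <- if (w == 0) 1 else sqrt(((n - 1) / n * w + b_over_n) / w)
    tibble::tibble(parameter = p, rhat = rhat)
  })
}

# ---- internals -------------------------------------------------------------

# annualized per-site arrays in list form
prepare_sites <- function(data, annualize, pf_sd_default) {
  stopifnot(inherits(data, "qm_data"))
  obs <- if (annualize) interpolate_annual(data$observations) else {
    data$observations
  }
  has_pf <- "plant_fraction" %in% names(obs)
  lapply(data$sites$site_id, function(id) {
    o <- obs[obs$site_id == id, ]
    site <- data$sites[data$sites$site_id == id, ]
    re <- data$re$re_norm[data$re$site_id == id]
    pf_keep <- if (has_pf) !is.na(o$plant_fraction) else rep(FALSE, nrow(o))
    sd_pf <- if (has_pf && any(pf_keep)) {
      s <- if ("plant_sd" %in% names(o)) mean(o$plant_sd, na.rm = TRUE) else {
        NA_real_
      }
      if (is.finite(s) && s > 0) s else pf_sd_default
    } else {
      pf_sd_default
    }
    list(
      site_id = id,
      t_soc = o$time_y, y_soc = o$soc_stock, sd_soc = mean(o$sd),
      t_pf = o$time_y[pf_keep],
      y_pf = if (any(pf_keep)) o$plant_fraction[pf_keep] else numeric(),
      sd_pf = sd_pf,
      css = site$css, clay = site$clay,
      re = if (length(re) == 1) re else 1
    )
  })
}

# parameter vector layout, proposal blocks and local-index matrix (0-based)
param_layout <- function(site_ids, parameterization) {
  if (parameterization == "local") {
    par_names <- c("u0", "eta11",
                   unlist(lapply(site_ids, function(id) {
                     paste0(c("q0_", "e0_", "beta0_"), id)
                   })))
    n_sites <- length(site_ids)
    local_idx0 <- matrix(0L, n_sites, 3)
    blocks0 <- list(c(0L, 1L))
    block_site0 <- -1L
    for (s in seq_len(n_sites)) {
      idx <- 2L + (s - 1L) * 3L + 0:2
      local_idx0[s, ] <- idx
      blocks0 <- c(blocks0, list(idx))
      block_site0 <- c(block_site0, s - 1L)
    }
    block_names <- c("generic", paste0("local_", site_ids))
  } else {
    par_names <- c("u0", "eta11", "q0", "e0", "beta0")
    n_sites <- length(site_ids)
    local_idx0 <- matrix(rep(c(2L, 3L, 4L), each = n_sites), n_sites, 3)
    blocks0 <- list(c(0L, 1L), c(2L, 3L, 4L))
    block_site0 <- c(-1L, -1L)
    block_names <- c("generic", "shared_locals")
  }
  # a joint move over all parameters picks up correlations (e.g. between
  # eta11 and the site efficiencies) that the structured blocks cannot
  blocks0 <- c(blocks0, list(seq_along(par_names) - 1L))
  block_site0 <- c(block_site0, -1L)
  block_names <- c(block_names, "joint")
  base <- vapply(par_names, function(nm) sub("_.*$", "", nm), "")
  list(par_names = par_names, base = base, blocks0 = blocks0,
       block_site0 = as.integer(block_site0), local_idx0 = local_idx0,
       block_names = block_names)
}

# prior matrix rows aligned with the parameter vector
build_prior_spec <- function(layout, priors) {
  rows <- lapply(layout$base, function(bn) {
    r <- priors[priors$parameter == bn, ]
    if (nrow(r) != 1) stop("no prior for parameter ", bn, call. = FALSE)
    z <- if (r$dist == "tnorm") pnorm_range(r$mean, r$sd, r$lower, r$upper) else 1
    c(dist = if (r$dist == "uniform") 0 else 1,
      mean = ifelse(is.na(r$mean), 0, r$mean),
      sd = ifelse(is.na(r$sd), 1, r$sd),
      lower = r$lower, upper = r$upper, log_z = log(z))
  })
  do.call(rbind, rows)
}

# prior draw rejected until structurally valid for every site
draw_valid_init <- function(layout, priors, prep, max_tries = 1000) {
  clay <- vapply(prep, `[[`, 0, "clay")
  for (i in seq_len(max_tries)) {
    init <- vapply(seq_along(layout$base), function(j) {
      sample_prior(1, layout$base[j], priors)
    }, 0)
    names(init) <- layout$par_names
    ok <- TRUE
    for (s in seq_along(prep)) {
      idx <- layout$local_idx0[s, ] + 1L
      v <- validate_parameters(init[1], init[2], init[idx[1]], init[idx[2]],
                               init[idx[3]], clay[s])
      if (!v$valid) { ok <- FALSE; break }
    }
    if (ok) return(unname(init))
  }
  stop("could not initialize chain: no valid parameter set found in ",
       max_tries, " prior draws (check priors and validity rules)",
       call. = FALSE)
}
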