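# shared fixture builders (everything generated in code)

# draw one structurally valid parameter set uniformly from the prior box
draw_prior_params <- function(priors = qm_priors(), clay = 17) {
  repeat {
    p <- c(
      u0 = sample_prior(1, "u0", priors),
      eta11 = sample_prior(1, "eta11", priors),
      q0 = sample_prior(1, "q0", priors),
      e0 = sample_prior(1, "e0", priors),
      beta0 = sample_prior(1, "beta0", priors)
    )
    v <- validate_parameters(p["u0"], p["eta11"], p["q0"], p["e0"],
                             p["beta0"], clay)
    if (v$valid) return(p)
  }
}

# small annual-sampling dataset with known truth, fast to calibrate
tiny_dataset <- function(n_sites = 2, seed = 1, duration = 30,
                         true_q0 = NULL, ...) {
  sites <- simulate_network(n_sites, seed = seed, true_q0 = true_q0, ...)
  sites$duration <- duration
  sites$end_year <- sites$start_year + as.integer(duration)
  weather <- simulate_climate(sites, seed = seed + 1)
  climate <- climate_scalars(weather, sites)
  re <- site_re(climate)
  obs <- simulate_observations(sites, re = re, annual = TRUE,
                               seed = seed + 2)
  qm_data(sites, obs, climate = climate, re = re)
}

# reference parameter list in the shape log_likelihood() expects
params_from_sites <- function(sites) {
  list(
    u0 = sites$true_u0[1],
    eta11 = sites$true_eta11[1],
    locals = tibble::tibble(
      site_id = sites$site_id, q0 = sites$true_q0,
      e0 = sites$true_e0, beta0 = sites$true_beta0
    )
  )
}
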