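test_that("log_likelihood is maximal at zero residuals and Gaussian in
           shape", {
  sites <- simulate_network(2, seed = 11)
  sites$duration <- 20
  sites$end_year <- sites$start_year + 20L
  obs <- simulate_observations(sites, annual = TRUE, noise_sd = 0,
                               plant_fractions = FALSE, seed = 12)
  obs$sd <- 2 # noiseless values with a declared error sd
  d <- qm_data(sites, obs)
  truth <- params_from_sites(sites)

  n <- nrow(interpolate_annual(obs))
  expect_equal(log_likelihood(truth, d), -n * log(2 * sqrt(2 * pi)))

  # a constant offset strictly decreases the likelihood
  shifted <- d
  shifted$observations$soc_stock <- shifted$observations$soc_stock + 1
  expect_lt(log_likelihood(truth, shifted), log_likelihood(truth, d))

  # doubling every sigma: closed-form Gaussian algebra
  # ll(2s) - ll(s) = -n log 2 + (3/8) sum(r^2)/s^2; here r = 1 everywhere
  d2 <- shifted
  d2$observations$sd <- 4
  expect_equal(log_likelihood(truth, d2) - log_likelihood(truth, shifted),
               -n * log(2) + (3 / 8) * n * 1 / 4, tolerance = 1e-9)

  # invalid parameters are rejected with -Inf, not an error
  bad <- truth
  bad$locals$e0 <- 0.99
  expect_identical(log_likelihood(bad, d), -Inf)
})

test_that("rmse_site reproduces closed-form residual summaries", {
  sites <- simulate_network(1, seed = 21)
  sites$duration <- 10
  sites$end_year <- sites$start_year + 10L
  obs <- simulate_observations(sites, annual = TRUE, noise_sd = 0,
                               plant_fractions = FALSE, seed = 22)
  obs$sd <- 1.5
  d <- qm_data(sites, obs)
  truth <- params_from_sites(sites)
  expect_equal(rmse_site(truth, d, "S01"), 0, tolerance = 1e-12)

  # constant residual d everywhere -> RMSE d
  d_off <- d
  d_off$observations$soc_stock <- d_off$observations$soc_stock + 2
  expect_equal(rmse_site(truth, d_off, "S01"), 2, tolerance = 1e-12)

  # residuals {3, 4} -> sqrt((9 + 16) / 2)
  two <- d
  two$observations <- two$observations[1:2, ]
  pred <- two$observations$soc_stock
  two$observations$soc_stock <- pred + c(3, 4)
  expect_equal(rmse_site(truth, two, "S01", annualize = FALSE),
               sqrt(12.5), tolerance = 1e-12)
  expect_error(rmse_site(truth, d, "S99"), "unknown site")
})

test_that("run_mcmc is reproducible, respects bounds, and records chains of
           the configured length", {
  d <- tiny_dataset(2, seed = 31, duration = 20)
  fit1 <- run_mcmc(d, n_chains = 2, n_iter = 1500, burn_in = 500, seed = 9)
  fit2 <- run_mcmc(d, n_chains = 2, n_iter = 1500, burn_in = 500, seed = 9)
  expect_identical(fit1$draws, fit2$draws)

  # chain length equals configured iterations (thin = 1)
  expect_equal(nrow(fit1$draws), 2 * 1500)
  expect_equal(max(fit1$draws$iteration), 1500)

  # every kept draw respects truncation bounds and structural validity
  post <- posterior_draws(fit1)
  pr <- qm_priors()
  for (id in c("S01", "S02")) {
    clay <- d$sites$clay[d$sites$site_id == id]
    v <- validate_parameters(post$u0, post$eta11, post[[paste0("q0_", id)]],
                             post[[paste0("e0_", id)]],
                             post[[paste0("beta0_", id)]], clay)
    expect_true(all(v$valid))
    expect_true(all(post[[paste0("q0_", id)]] >= 0.5 &
                      post[[paste0("q0_", id)]] <= 1.5))
    expect_true(all(post[[paste0("e0_", id)]] <= 0.6))
  }
  expect_true(all(post$eta11 <= 0.72 & post$u0 <= 0.98))
  expect_true(all(is.finite(post$log_post)))
  expect_true(all(post[paste0("rmse_", c("S01", "S02"))] >= 0))
})

test_that("run_mcmc supports thinning and the generic parameterization", {
  d <- tiny_dataset(2, seed = 41, duration = 20)
  fit <- run_mcmc(d, n_chains = 1, n_iter = 2000, burn_in = 400, thin = 4,
                  seed = 2)
  expect_equal(nrow(fit$draws), 500)
  gfit <- run_mcmc(d, n_chains = 1, n_iter = 2000, burn_in = 400, seed = 2,
                   parameterization = "generic")
  expect_setequal(
    setdiff(names(gfit$draws),
            c("chain", "iteration", "log_prior", "log_lik", "log_post",
              "rmse_S01", "rmse_S02")),
    c("u0", "eta11", "q0", "e0", "beta0"))
})

test_that("the recorded log posterior matches the reference likelihood and
           prior", {
  d <- tiny_dataset(2, seed = 51, duration = 20)
  fit <- run_mcmc(d, n_chains = 1, n_iter = 400, burn_in = 100, seed = 3)
  post <- posterior_draws(fit)
  for (i in c(1, 150, 299)) {
    pr <- list(
      u0 = post$u0[i], eta11 = post$eta11[i],
      locals = tibble::tibble(
        site_id = c("S01", "S02"),
        q0 = c(post$q0_S01[i], post$q0_S02[i]),
        e0 = c(post$e0_S01[i], post$e0_S02[i]),
        beta0 = c(post$beta0_S01[i], post$beta0_S02[i])))
    expect_equal(post$log_lik[i], log_likelihood(pr, d), tolerance = 1e-10)
    lp <- log_prior_density(post$u0[i], "u0") +
      log_prior_density(post$eta11[i], "eta11") +
      sum(vapply(c("S01", "S02"), function(id) {
        log_prior_density(post[[paste0("q0_", id)]][i], "q0") +
          log_prior_density(post[[paste0("e0_", id)]][i], "e0") +
          log_prior_density(post[[paste0("beta0_", id)]][i], "beta0")
      }, 0))
    expect_equal(post$log_prior[i], lp, tolerance = 1e-10)
  }
})

test_that("gelman_rubin matches a direct evaluation of the formula", {
  # exact copies: zero between-chain variance
  v <- rnorm(1000)
  copies <- tibble::tibble(chain = rep(1:2, each = 1000), x = c(v, v))
  expect_equal(gelman_rubin(copies, "x")$rhat, 1, tolerance = 1e-3)

  # gross non-mixing
  apart <- tibble::tibble(chain = rep(1:2, each = 500),
                          x = c(rnorm(500, 0), rnorm(500, 100)))
  expect_gt(gelman_rubin(apart, "x")$rhat, 10)

  # small hand dataset against a brute-force oracle
  set.seed(77)
  hand <- tibble::tibble(chain = rep(1:2, each = 10), x = rnorm(20))
  ch <- split(hand$x, hand$chain)
  n <- 10
  w <- mean(c(var(ch[[1]]), var(ch[[2]])))
  b_over_n <- var(c(mean(ch[[1]]), mean(ch[[2]])))
  oracle <- sqrt(((n - 1) / n * w + b_over_n) / w)
  expect_equal(gelman_rubin(hand, "x")$rhat, oracle, tolerance = 1e-12)

  single <- tibble::tibble(chain = 1, x = rnorm(100))
  expect_error(gelman_rubin(single, "x"), "2 chains")
})

test_that("tidy and glance summarise a fit", {
  d <- tiny_dataset(2, seed = 61, duration = 20)
  fit <- run_mcmc(d, n_chains = 2, n_iter = 1500, burn_in = 500, seed = 4)
  td <- tidy(fit)
  expect_setequal(td$parameter, fit$par_names)
  expect_true(all(td$conf.low <= td$median & td$median <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_chains, 2)
  expect_equal(gl$n_draws, 2 * 1000)
  expect_true(is.finite(gl$max_rhat))
})
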