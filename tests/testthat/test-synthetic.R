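test_that("simulate_network is seeded, in range, and structurally shared", {
  s1 <- simulate_network(5, seed = 7)
  s2 <- simulate_network(5, seed = 7)
  expect_identical(s1, s2)
  r <- network_ranges()
  expect_true(all(s1$css >= r$css[1] & s1$css <= r$css[2]))
  expect_true(all(s1$clay >= r$clay[1] & s1$clay <= r$clay[2]))
  expect_true(all(s1$duration >= r$duration[1] &
                    s1$duration <= r$duration[2]))
  # shared generic kinetics, heterogeneous initial quality
  expect_equal(length(unique(s1$true_u0)), 1)
  expect_equal(length(unique(s1$true_eta11)), 1)
  expect_gt(length(unique(s1$true_q0)), 1)
  expect_true(all(abs(s1$clay + s1$silt + s1$sand - 100) < 1e-9))
  expect_error(simulate_network(0), "n_sites")
  expect_error(simulate_network(2, ranges = list(css = c(3, 1))), "range")
})

test_that("simulate_climate fluctuates around the site normals", {
  sites <- simulate_network(3, seed = 17)
  w1 <- simulate_climate(sites, seed = 18)
  w2 <- simulate_climate(sites, seed = 18)
  expect_identical(w1, w2)
  expect_true(all(w1$precip_mm >= 0))
  const <- simulate_climate(sites, seed = 18, tmean_sd = 0, precip_cv = 0)
  for (id in sites$site_id) {
    expect_equal(unique(const$tmean_c[const$site_id == id]),
                 sites$mat_c[sites$site_id == id])
  }
})

test_that("simulate_observations reproduces the closed-form model under zero
           noise", {
  sites <- simulate_network(2, seed = 27)
  obs <- simulate_observations(sites, noise_sd = 0, pf_noise_sd = 0,
                               seed = 28)
  for (id in sites$site_id) {
    s <- sites[sites$site_id == id, ]
    o <- obs[obs$site_id == id, ]
    beta <- effective_beta(s$true_beta0, s$clay)
    expect_equal(o$soc_stock,
                 soc_stock(o$time_y, s$css, s$true_q0, beta, s$true_eta11,
                           s$true_u0, s$true_e0))
    expect_equal(o$plant_fraction,
                 plant_fraction(o$time_y, s$true_q0, beta, s$true_e0,
                                s$true_u0))
    expect_equal(o$soc_stock[o$time_y == 0], s$css)
    # irregular schedule includes both endpoints
    expect_true(all(c(0, s$duration) %in% o$time_y))
  }
  expect_error(
    simulate_observations(sites, schedule = list(S01 = c(-1, 5),
                                                 S02 = c(0, 5))),
    "precede")
})

test_that("noisy observations are unbiased around the model value", {
  sites <- simulate_network(1, seed = 37)
  sites$duration <- 20
  sites$end_year <- sites$start_year + 20L
  # 1000 replicate observations at the same times via repeated seeds
  reps <- purrr::map_dfr(1:1000, function(i) {
    simulate_observations(sites, schedule = list(S01 = c(0, 10, 20)),
                          noise_sd = 1.5, plant_fractions = FALSE,
                          seed = i)
  })
  s <- sites[1, ]
  truth <- soc_stock(10, s$css, s$true_q0,
                     effective_beta(s$true_beta0, s$clay), s$true_eta11,
                     s$true_u0, s$true_e0)
  at10 <- reps$soc_stock[reps$time_y == 10]
  se <- 1.5 / sqrt(length(at10))
  expect_lt(abs(mean(at10) - truth), 3 * se)
})

test_that("simulate_ltbf assembles a coherent calibration dataset", {
  d <- simulate_ltbf(n_sites = 3, seed = 47, n_obs = 8)
  expect_s3_class(d, "qm_data")
  expect_equal(nrow(d$sites), 3)
  expect_equal(mean(d$re$re_norm), 1, tolerance = 1e-12)
  expect_true(all(d$observations$site_id %in% d$sites$site_id))
  expect_true(all(d$observations$plant_fraction >= 0 &
                    d$observations$plant_fraction <= 1))
  expect_identical(simulate_ltbf(n_sites = 3, seed = 47, n_obs = 8)$observations,
                   d$observations)
})
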