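# Closed-form kinetics: frozen oracle values were computed independently by
# direct formula evaluation (and deSolve integration for the plant pool)
# before being asserted here.

test_that("effective_beta adds the clay term to beta0", {
  expect_equal(effective_beta(0.7, 0), 0.7)
  expect_equal(effective_beta(0.7, 36), 1.06)
  expect_equal(effective_beta(0.7, 17), 0.87)
  expect_error(effective_beta(-0.1, 10), "beta0")
  expect_error(effective_beta(0.7, -5), "clay")
  expect_error(effective_beta(0.7, 120), "clay")
})

test_that("mean_quality matches the closed form and decreases in time", {
  expect_equal(mean_quality(0, 1.08, 0.87, 0.36, 0.49), 1.08)
  expect_equal(mean_quality(10, 1.08, 0.87, 0.36, 0.49, 1),
               0.353704933565, tolerance = 1e-9)
  # property: strictly decreasing and bounded in (0, q0] over the prior box
  set.seed(101)
  for (i in 1:25) {
    p <- draw_prior_params()
    beta <- effective_beta(p["beta0"], 17)
    q <- mean_quality(c(0, 5, 10, 20, 40, 80), p["q0"], beta, p["eta11"],
                      p["u0"])
    expect_true(all(diff(q) < 0))
    expect_true(all(q > 0 & q <= p["q0"]))
  }
})

test_that("mean_quality is vectorized consistently over time and parameters", {
  tt <- c(0, 3, 7, 50)
  one_by_one <- vapply(tt, mean_quality, 0, q0 = 1.1, beta = 0.9,
                       eta11 = 0.3, u0 = 0.4)
  expect_equal(mean_quality(tt, 1.1, 0.9, 0.3, 0.4), one_by_one)
})

test_that("mean_quality converges to the exponential limit as beta -> 0", {
  tt <- seq(0, 80, by = 5)
  exact <- mean_quality(tt, 1.08, 1e-6, 0.36, 0.49)
  limit <- 1.08 * exp(-0.36 * 0.49 * 1.08^1e-6 * tt)
  expect_lt(max(abs(exact / limit - 1)), 1e-4)
  # below the tolerance the limiting form is used and stays finite
  expect_equal(mean_quality(10, 1.08, 1e-12, 0.36, 0.49),
               1.08 * exp(-0.36 * 0.49 * 1.08^1e-12 * 10))
})

test_that("decay_exponent follows the bracket formula and guards e0", {
  expect_equal(decay_exponent(0.3, 0.36, 0.87), 5.61148148148,
               tolerance = 1e-10)
  expect_equal(decay_exponent(0.5, 0.5, 1.0), 1.0)
  expect_error(decay_exponent(0, 0.36, 0.87), "e0")
  expect_error(decay_exponent(1, 0.36, 0.87), "e0")
})

test_that("soc_stock starts at Css, decays strictly, and has no inert floor", {
  expect_equal(soc_stock(0, 65.5, 1.08, 0.87, 0.36, 0.05, 0.3), 65.5)
  expect_equal(soc_stock(10, 65.5, 1.08, 0.87, 0.36, 0.05, 0.3, 1),
               24.130670421, tolerance = 1e-8)
  set.seed(202)
  for (i in 1:25) {
    p <- draw_prior_params()
    beta <- effective_beta(p["beta0"], 17)
    s <- soc_stock(c(0, 10, 100, 300, 1000, 3000), 65.5, p["q0"], beta,
                   p["eta11"], p["u0"], p["e0"])
    expect_true(all(diff(s) < 0))
    expect_true(all(s > 0))
    expect_equal(s[1], 65.5)
  }
})

test_that("soc_stock rejects parameter sets with a non-positive exponent", {
  # e0 = 0.9, eta11 = 0.7 gives (1-e0)/(eta11 e0) ~ 0.159 < beta
  expect_error(soc_stock(10, 65.5, 1.08, 0.87, 0.7, 0.05, 0.9),
               "decay exponent")
})

test_that("initial_som_quality is below q0 and linear in q0", {
  expect_equal(initial_som_quality(1.08, 0.3, 0.36, 0.87),
               0.916647806846, tolerance = 1e-9)
  # eta11 = 0 collapses the ratio to 1
  expect_equal(initial_som_quality(1.08, 0.3, 0, 0.87), 1.08)
  set.seed(303)
  for (i in 1:25) {
    p <- draw_prior_params()
    beta <- effective_beta(p["beta0"], 17)
    iq <- initial_som_quality(p["q0"], p["e0"], p["eta11"], beta)
    expect_lt(iq, p[["q0"]])
    # linearity in q0
    expect_equal(initial_som_quality(2 * p["q0"], p["e0"], p["eta11"], beta),
                 2 * iq, ignore_attr = TRUE)
  }
  expect_error(initial_som_quality(1.08, 0.99, 0.36, 0.87), "positive")
})

test_that("steady_state_plant_pool is linear in the input rate", {
  expect_equal(steady_state_plant_pool(0, 0.3, 0.05, 1.08, 0.87), 0)
  expect_equal(steady_state_plant_pool(1, 0.3, 0.05, 1.08, 0.87),
               5.61141751136, tolerance = 1e-9)
  expect_equal(steady_state_plant_pool(2, 0.3, 0.05, 1.08, 0.87),
               2 * steady_state_plant_pool(1, 0.3, 0.05, 1.08, 0.87))
  expect_error(steady_state_plant_pool(1, 0.3, 0, 1.08, 0.87), "u0")
})

test_that("plant_fraction supports both rate conventions", {
  expect_equal(plant_fraction(0, 1.08, 0.87, 0.3, 0.05), 1.0)
  expect_equal(plant_fraction(10, 1.08, 0.87, 0.3, 0.05, 1, "decay_rate"),
               0.168287592077, tolerance = 1e-8)
  expect_equal(plant_fraction(1, 1.08, 0.87, 0.3, 0.05, 1, "reciprocal"),
               0.00365588342674, tolerance = 1e-8)
  expect_error(plant_fraction(1, 1.08, 0.87, 0.3, 0.05, 1, "what"))
  # climate scaling enters wherever u0 does: re = 2 halves the time scale
  expect_equal(plant_fraction(5, 1.08, 0.87, 0.3, 0.05, re = 2),
               plant_fraction(10, 1.08, 0.87, 0.3, 0.05, re = 1))
  set.seed(404)
  p <- draw_prior_params()
  pf <- plant_fraction(c(0, 1, 40), p["q0"], 0.9, p["e0"], p["u0"])
  expect_true(all(pf > 0 & pf <= 1))
})

test_that("validate_parameters reports each violated rule", {
  v <- validate_parameters(0.49, 0.36, 1.08, 0.3, 0.7, 17)
  expect_true(v$valid)
  expect_length(v$violations[[1]], 0)

  v <- validate_parameters(0.49, 0.36, 1.08, 0.99, 0.7, 17)
  expect_false(v$valid)

  v <- validate_parameters(-1, 0.36, 1.08, 0.3, 0.7, 17)
  expect_false(v$valid)
  expect_match(v$violations[[1]], "positivity: u0", all = FALSE)

  # e0 high enough to break the equilibrium-quality precondition
  v <- validate_parameters(0.49, 0.36, 1.08, 0.8, 0.7, 17)
  expect_false(v$valid)

  # vectorized over sites
  v <- validate_parameters(0.49, 0.36, c(1.08, 0.9), c(0.3, 0.3),
                           c(0.7, 0.7), c(17, 36))
  expect_equal(nrow(v), 2)
  expect_true(all(v$valid))
})
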