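test_that("temperature_response is an Arrhenius curve capped at 1", {
  expect_equal(temperature_response(35.14), 1.0)
  expect_equal(temperature_response(40), 1.0)
  # oracle: direct Arrhenius arithmetic with R_gas = 8.314 J mol^-1 K^-1
  expect_equal(temperature_response(10), 0.127492099754, tolerance = 1e-8)
  # continuity at the cap
  expect_equal(temperature_response(35.14 - 1e-9), 1.0, tolerance = 1e-6)
  # monotone increasing below the cap, always in (0, 1]
  tt <- seq(-20, 35, by = 1)
  r <- temperature_response(tt)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r <= 1))
  expect_error(temperature_response(10, ea = -5), "ea")
})

test_that("the classic empirical temperature form behaves like a capped
           reduction function too", {
  r <- temperature_response(seq(-10, 45, by = 1), form = "lloyd_taylor")
  expect_true(all(r > 0 & r <= 1))
  expect_equal(temperature_response(35.14, form = "lloyd_taylor"), 1.0)
})

test_that("moisture_response is unimodal with its optimum at s*", {
  expect_equal(moisture_response(0), 0)
  expect_equal(moisture_response(0.65), 1.0)
  s <- seq(0, 1, by = 0.01)
  r <- moisture_response(s)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(which.max(r), which(s == 0.65))
  expect_error(moisture_response(1.2), "saturation")
  # pluggable curve
  expect_equal(moisture_response(c(0.2, 0.8), curve = function(s) s),
               c(0.2, 0.8))
  expect_error(moisture_response(0.5, curve = function(s) s * 3), "0, 1")
})

test_that("potential_evapotranspiration responds to energy and dryness", {
  # no radiative energy and saturated air: nothing drives evaporation
  expect_lt(potential_evapotranspiration(15, rad = 0, rh = 1, wind = 2), 1)
  # linear in the scaling term
  expect_equal(
    potential_evapotranspiration(10, rad = 8, rh = 0.7, wind = 2,
                                 scale = 0.9),
    0.9 * potential_evapotranspiration(10, rad = 8, rh = 0.7, wind = 2,
                                       scale = 1))
  # drier air (larger vapour-pressure deficit) never lowers PET
  wet <- potential_evapotranspiration(10, rad = 8, rh = 0.9, wind = 2)
  dry <- potential_evapotranspiration(10, rad = 8, rh = 0.5, wind = 2)
  expect_gte(dry, wet)
  # temperature-based fallback warns but returns a plausible total
  expect_warning(pet <- potential_evapotranspiration(10), "Hamon")
  expect_gt(pet, 0)
})

test_that("water_balance conserves water and keeps saturation in [0, 1]", {
  wb <- water_balance(precip = rep(900, 10), pet = rep(400, 10), whc = 120)
  expect_equal(wb$saturation[10], 1)         # wet climate fills the bucket
  expect_true(all(wb$aet <= wb$pet + 1e-12)) # actual ET bounded by PET
  dry <- water_balance(precip = rep(0, 10), pet = rep(500, 10), whc = 120)
  expect_true(all(diff(dry$saturation) <= 0))
  # bookkeeping identity at every step
  store_prev <- c(120, wb$store[-10])
  expect_equal(wb$store - store_prev, wb$precip - wb$aet - wb$drainage,
               tolerance = 1e-9)
  expect_true(all(wb$saturation >= 0 & wb$saturation <= 1))
  expect_error(water_balance(1:3, 1:3, whc = 0), "whc")
  expect_error(water_balance(1:3, 1:4, whc = 100), "aligned")
})

test_that("climate_scalars multiplies responses and normalizes across sites", {
  sites <- simulate_network(3, seed = 5)
  weather <- simulate_climate(sites, seed = 6)
  cs <- climate_scalars(weather, sites)
  expect_true(all(c("re_temp", "r_moist", "re_raw", "re_norm") %in%
                    names(cs)))
  expect_equal(cs$re_raw, cs$re_temp * cs$r_moist)
  expect_true(all(cs$re_raw >= 0 & cs$re_raw <= 1))
  # cross-site mean of the per-site mean normalized scalar is exactly 1
  re <- site_re(cs)
  expect_equal(mean(re$re_norm), 1, tolerance = 1e-12)
  expect_true(all(re$re_norm > 0))
})

test_that("identical sites get identical (unit) normalized scalars", {
  sites <- simulate_network(2, seed = 5)
  sites[2, c("clay", "silt", "sand", "depth_cm", "mat_c", "map_mm")] <-
    sites[1, c("clay", "silt", "sand", "depth_cm", "mat_c", "map_mm")]
  weather <- simulate_climate(sites, seed = 6, tmean_sd = 0, precip_cv = 0)
  re <- site_re(climate_scalars(weather, sites))
  expect_equal(re$re_norm, c(1, 1), tolerance = 1e-12)
})
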