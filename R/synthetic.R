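# Synthetic multi-site bare-fallow networks.
#
# Emulates the statistical structure of the European long-term bare-fallow
# network: a handful of sites with contrasting texture, climate and initial
# stocks, SOC stock series decaying from a steady state with Gaussian
# replicate noise and irregular sampling, optional plant-derived-fraction
# series, and annual weather. True parameters are drawn with heterogeneous
# initial litter quality q0 across sites but shared generic kinetics
# (u0, eta11), the structural assumption the calibration tests.

#' Default ranges for synthetic site networks
#'
#' Spans mirroring the European bare-fallow network: initial stocks 40--100
#' Mg C ha^-1, clay 7--36 %, mean annual temperature 5.4--10.7 degC, annual
#' precipitation 533--862 mm, durations 30--80 years, sampling depth
#' 20--25 cm.
#'
#' @return A named list of length-2 numeric ranges.
#' @export
network_ranges <- function() {
  list(
    css = c(40, 100),
    clay = c(7, 36),
    mat_c = c(5.4, 10.7),
    map_mm = c(533, 862),
    duration = c(30, 80),
    depth_cm = c(20, 25),
    q0 = c(0.9, 1.3)
  )
}

#' Generate a synthetic site network
#'
#' Draws `n_sites` site profiles with texture, depth, initial stock, climate
#' normals and experiment duration uniformly within `ranges`, plus the true
#' Q-model parameters used by the forward simulator: shared generic kinetics
#' (`true_u0`, `true_eta11`) and site-local `true_q0` (heterogeneous across
#' sites), `true_e0`, `true_beta0`.
#'
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed; the network is fully reproducible from it.
#' @param ranges Named list of ranges as in [network_ranges()].
#' @param true_u0,true_eta11 Shared generic kinetic values. Defaults 0.05 and
#'   0.36.
#' @param true_q0 Either `NULL` (drawn uniformly within `ranges$q0` per site)
#'   or a vector of length `n_sites`.
#' @param true_e0,true_beta0 Local parameter values, recycled across sites.
#'   Defaults 0.3 and 0.7.
#' @return A tibble with one row per site: `site_id`, `clay`, `silt`, `sand`,
#'   `depth_cm`, `css`, `duration`, `start_year`, `end_year`, `mat_c`,
#'   `map_mm` and the `true_*` parameter columns.
#' @examples
#' simulate_network(4, seed = 1)
#' @export
simulate_network <- function(n_sites = 4, seed = 1, ranges = network_ranges(),
                             true_u0 = 0.05, true_eta11 = 0.36,
                             true_q0 = NULL, true_e0 = 0.3,
                             true_beta0 = 0.7) {
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  for (r in ranges) {
    if (length(r) != 2 || r[2] < r[1]) {
      stop("each range must be a non-empty (lo, hi) pair", call. = FALSE)
    }
  }
  withr_seed(seed, {
    draw <- function(name) runif(n_sites, ranges[[name]][1],
                                 ranges[[name]][2])
    clay <- draw("clay")
    # split the remainder between silt and sand
    silt_share <- runif(n_sites, 0.3, 0.7)
    silt <- (100 - clay) * silt_share
    sand <- 100 - clay - silt
    if (is.null(true_q0)) true_q0 <- draw("q0")
    if (length(true_q0) != n_sites) {
      stop("true_q0 must have one value per site", call. = FALSE)
    }
    duration <- round(draw("duration"))
    tibble::tibble(
      site_id = sprintf("S%02d", seq_len(n_sites)),
      clay = clay, silt = silt, sand = sand,
      depth_cm = round(draw("depth_cm")),
      css = draw("css"),
      duration = duration,
      start_year = 1956L,
      end_year = 1956L + as.integer(duration),
      mat_c = draw("mat_c"),
      map_mm = draw("map_mm"),
      true_u0 = true_u0, true_eta11 = true_eta11,
      true_q0 = true_q0,
      true_e0 = rep_len(true_e0, n_sites),
      true_beta0 = rep_len(true_beta0, n_sites)
    )
  })
}

#' Generate annual weather for a site network
#'
#' Seeded Gaussian interannual fluctuations around each site's climate
#' normals: temperature with standard deviation `tmean_sd` (degC),
#' precipitation with coefficient of variation `precip_cv`, truncated at
#' zero.
#'
#' @param sites A site tibble from [simulate_network()].
#' @param seed Integer seed.
#' @param tmean_sd Interannual temperature standard deviation (degC).
#'   Default 0.8.
#' @param precip_cv Interannual precipitation coefficient of variation.
#'   Default 0.12.
#' @return A tibble with columns `site_id`, `year`, `tmean_c`, `precip_mm`.
#' @export
simulate_climate <- function(sites, seed = 1, tmean_sd = 0.8,
                             precip_cv = 0.12) {
  withr_seed(seed, {
    purrr::pmap_dfr(
      dplyr::select(sites, "site_id", "start_year", "end_year", "mat_c",
                    "map_mm"),
      function(site_id, start_year, end_year, mat_c, map_mm) {
        years <- seq(start_year, end_year)
        tibble::tibble(
          site_id = site_id,
          year = years,
          tmean_c = rnorm(length(years), mat_c, tmean_sd),
          precip_mm = pmax(0, rnorm(length(years), map_mm,
                                    precip_cv * map_mm))
        )
      }
    )
  })
}

#' Generate noisy bare-fallow observations
#'
#' Runs the closed-form Q model forward from each site's true parameters and
#' adds seeded Gaussian observation noise: SOC stocks with standard deviation
#' `noise_sd` (Mg C ha^-1), plant-derived fractions with standard deviation
#' `pf_noise_sd` truncated to \[0, 1\]. Sampling times default to an irregular
#' schedule (`n_obs` distinct years drawn without replacement, always
#' including the first and last year), mirroring how bare-fallow archives are
#' actually sampled; `annual = TRUE` samples every year.
#'
#' @param sites A site tibble from [simulate_network()] (needs the `true_*`
#'   columns, `css`, `clay` and `duration`).
#' @param re Either a tibble with columns `site_id`, `re_norm` (e.g. from
#'   [site_re()]) or `NULL` for a neutral climate scalar of 1 at every site.
#' @param n_obs Number of sampling occasions per site (ignored when
#'   `schedule` or `annual` is given). Default 12.
#' @param schedule Optional list of explicit sampling-year vectors, named by
#'   `site_id`; years count from 0 at the experiment start.
#' @param annual If `TRUE`, sample every integer year from 0 to the duration.
#' @param noise_sd SOC observation noise standard deviation
#'   (Mg C ha^-1, non-negative). Default 1.5.
#' @param pf_noise_sd Plant-fraction noise standard deviation. Default 0.05.
#' @param plant_fractions If `TRUE` (default), include a plant-derived
#'   fraction series for every site.
#' @param rate_convention Passed to [plant_fraction()].
#' @param seed Integer seed.
#' @return An observation tibble: `site_id`, `time_y`, `soc_stock`, `sd`,
#'   and (optionally) `plant_fraction`, `plant_sd`.
#' @export
simulate_observations <- function(sites, re = NULL, n_obs = 12,
                                  schedule = NULL, annual = FALSE,
                                  noise_sd = 1.5, pf_noise_sd = 0.05,
                                  plant_fractions = TRUE,
                                  rate_convention = "decay_rate",
                                  seed = 1) {
  if (noise_sd < 0 || pf_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  re_tbl <- resolve_re(sites, re)
  withr_seed(seed, {
    purrr::pmap_dfr(
      dplyr::select(sites, "site_id", "css", "clay", "duration",
                    dplyr::starts_with("true_")),
      function(site_id, css, clay, duration, true_u0, true_eta11, true_q0,
               true_e0, true_beta0) {
        times <- if (!is.null(schedule)) {
          sort(unique(schedule[[site_id]]))
        } else if (annual) {
          0:duration
        } else {
          inner <- sample(seq_len(duration - 1), min(n_obs - 2, duration - 1))
          sort(unique(c(0, inner, duration)))
        }
        if (any(times < 0)) {
          stop("sampling schedule must not precede the experiment start",
               call. = FALSE)
        }
        if (any(times > duration)) {
          stop("sampling schedule exceeds the experiment span", call. = FALSE)
        }
        beta <- effective_beta(true_beta0, clay)
        re_i <- re_tbl$re_norm[re_tbl$site_id == site_id]
        truth <- soc_stock(times, css, true_q0, beta, true_eta11, true_u0,
                           true_e0, re_i)
        out <- tibble::tibble(
          site_id = site_id,
          time_y = times,
          soc_stock = truth + rnorm(length(times), 0, noise_sd),
          sd = noise_sd
        )
        if (plant_fractions) {
          pf <- plant_fraction(times, true_q0, beta, true_e0, true_u0, re_i,
                               rate_convention)
          out$plant_fraction <- pmin(1, pmax(0, pf + rnorm(length(times), 0,
                                                           pf_noise_sd)))
          out$plant_sd <- pf_noise_sd
        }
        out
      }
    )
  })
}

#' Simulate a complete bare-fallow dataset
#'
#' Convenience wrapper chaining [simulate_network()], [simulate_climate()],
#' [climate_scalars()] and [simulate_observations()] into a single
#' calibration-ready dataset. The climate scalar used to generate the
#' observations is the same per-site normalized scalar the calibration will
#' see, so the pipeline is closed end to end.
#'
#' @inheritParams simulate_network
#' @inheritParams simulate_observations
#' @param ... Passed on to [simulate_network()].
#' @return A [qm_data()] object with `sites`, `observations`, `climate` and
#'   `re` components.
#' @examples
#' d <- simulate_ltbf(n_sites = 3, seed = 7, n_obs = 8)
#' d$observations
#' @export
simulate_ltbf <- function(n_sites = 4, seed = 1, n_obs = 12, annual = FALSE,
                          noise_sd = 1.5, pf_noise_sd = 0.05,
                          plant_fractions = TRUE, ...) {
  sites <- simulate_network(n_sites, seed = seed, ...)
  weather <- simulate_climate(sites, seed = seed + 1000L)
  climate <- climate_scalars(weather, sites)
  re <- site_re(climate)
  obs <- simulate_observations(
    sites, re = re, n_obs = n_obs, annual = annual, noise_sd = noise_sd,
    pf_noise_sd = pf_noise_sd, plant_fractions = plant_fractions,
    seed = seed + 2000L
  )
  qm_data(sites, obs, climate = climate, re = re)
}

resolve_re <- function(sites, re) {
  if (is.null(re)) {
    tibble::tibble(site_id = sites$site_id, re_norm = 1)
  } else if (is.data.frame(re)) {
    missing <- setdiff(sites$site_id, re$site_id)
    if (length(missing) > 0) {
      stop("re is missing sites: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    re
  } else {
    tibble::tibble(site_id = sites$site_id,
                   re_norm = rep_len(re, nrow(sites)))
  }
}

# internal: evaluate expr under a temporary seed, restoring RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
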