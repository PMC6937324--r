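# Per-site climate reduction scalar r_e built from annual weather.
#
# Temperature and moisture each give a reduction factor in [0, 1]; their
# product re_raw is averaged over years per site and normalized by the grand
# mean across sites, so the calibrated metabolic rate u0 refers to an average
# climate and re_norm carries the between-site climatic differences.

#' Temperature reduction function
#'
#' Arrhenius-type response of decomposition to annual mean air temperature,
#' normalized to 1 at the capping temperature `t_cap` and clamped to 1 above
#' it, so the value is a reduction factor in (0, 1]. The activation energy
#' default (59.46 kJ mol^-1) is the average measured on decades-old
#' bare-fallow SOC; the cap (35.14 degC) is the temperature at which the
#' response saturates.
#'
#' `form = "lloyd_taylor"` instead uses the classic empirical soil-respiration
#' response `exp(308.56 * (1/56.02 - 1/(T + 46.02)))` (temperature in degC),
#' normalized and capped the same way.
#'
#' @param tmean Annual mean air temperature (degC).
#' @param ea Activation energy (kJ mol^-1, > 0). Default 59.46.
#' @param t_cap Capping temperature (degC). Default 35.14.
#' @param form `"arrhenius"` (default) or `"lloyd_taylor"`.
#' @return Reduction factor in (0, 1].
#' @examples
#' temperature_response(c(5, 10, 20, 40))
#' @export
temperature_response <- function(tmean, ea = 59.46, t_cap = 35.14,
                                 form = c("arrhenius", "lloyd_taylor")) {
  form <- match.arg(form)
  if (!is.numeric(ea) || ea <= 0) stop("ea must be positive", call. = FALSE)
  check_num(tmean, "tmean", lower = -273.15, strict = TRUE, upper = Inf)
  r_gas <- 8.314 # J mol^-1 K^-1
  if (form == "arrhenius") {
    f <- exp(-(ea * 1000 / r_gas) *
               (1 / (tmean + 273.15) - 1 / (t_cap + 273.15)))
  } else {
    lt <- function(tc) exp(308.56 * (1 / 56.02 - 1 / (tc + 273.15 - 227.13)))
    f <- lt(tmean) / lt(t_cap)
  }
  pmin(f, 1)
}

#' Moisture reduction function
#'
#' Response of decomposition to the soil water saturation fraction. The
#' default curve is a documented piecewise polynomial: zero at complete
#' dryness, rising as `x * (2 - x)` (with `x = saturation / optimum`) to 1 at
#' the optimum saturation, then declining quadratically to `sat_value` at
#' full saturation (oxygen limitation). Any alternative curve can be plugged
#' in as a function of saturation returning values in \[0, 1\].
#'
#' @param saturation Soil water saturation fraction, in \[0, 1\].
#' @param optimum Saturation at which decomposition peaks. Default 0.65.
#' @param sat_value Value of the curve at saturation 1. Default 0.6.
#' @param curve Optional replacement response: a function of the saturation
#'   vector returning values in \[0, 1\].
#' @return Reduction factor in \[0, 1\].
#' @examples
#' moisture_response(c(0, 0.325, 0.65, 1))
#' @export
moisture_response <- function(saturation, optimum = 0.65, sat_value = 0.6,
                              curve = NULL) {
  check_num(saturation, "saturation", lower = 0, upper = 1)
  if (!is.null(curve)) {
    out <- curve(saturation)
    if (any(out < 0 | out > 1)) {
      stop("custom moisture curve returned values outside [0, 1]",
           call. = FALSE)
    }
    return(out)
  }
  if (optimum <= 0 || optimum >= 1) stop("optimum must be in (0, 1)",
                                         call. = FALSE)
  x <- saturation / optimum
  rising <- x * (2 - x)
  falling <- 1 - (1 - sat_value) * ((saturation - optimum) / (1 - optimum))^2
  ifelse(saturation <= optimum, rising, falling)
}

#' Potential evapotranspiration from annual weather
#'
#' Annual reference evapotranspiration. With net radiation, relative humidity
#' and wind speed available, the Penman-Monteith reference formulation (FAO-56
#' form, grass reference) is evaluated on the annual means and scaled to a
#' yearly total; a multiplicative scale (default 0.9, an empirical bare-soil
#' correction) is then applied. When any of radiation, humidity or wind is
#' missing, a documented temperature-based approximation (Hamon) is used
#' instead and a warning is issued.
#'
#' @param tmean Annual mean air temperature (degC).
#' @param rad Net radiation, annual mean (MJ m^-2 day^-1), or `NULL`.
#' @param rh Relative humidity as a fraction in \[0, 1\], or `NULL`.
#' @param wind Wind speed at 2 m (m s^-1), or `NULL`.
#' @param scale Multiplicative scaling term. Default 0.9.
#' @param elevation Site elevation (m), used for atmospheric pressure.
#' @return Potential evapotranspiration (mm per year, >= 0).
#' @examples
#' potential_evapotranspiration(10, rad = 8, rh = 0.75, wind = 2)
#' potential_evapotranspiration(10) # falls back with a warning
#' @export
potential_evapotranspiration <- function(tmean, rad = NULL, rh = NULL,
                                         wind = NULL, scale = 0.9,
                                         elevation = 0) {
  check_num(tmean, "tmean", lower = -273.15, strict = TRUE, upper = Inf)
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3)) # kPa
  if (is.null(rad) || is.null(rh) || is.null(wind)) {
    warning("radiation/humidity/wind missing: using temperature-based ",
            "(Hamon) PET approximation", call. = FALSE)
    # Hamon with a 12-h daylength factor; 216.7 * es[mb] / (T + 273.3) is the
    # saturated absolute humidity in g m^-3
    pet_day <- 0.1651 * 216.7 * (es * 10) / (tmean + 273.3)
  } else {
    if (any(rad < 0)) stop("rad must be non-negative", call. = FALSE)
    check_num(rh, "rh", lower = 0, upper = 1)
    if (any(wind < 0)) stop("wind must be non-negative", call. = FALSE)
    delta <- 4098 * es / (tmean + 237.3)^2
    pressure <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
    gamma <- 0.000665 * pressure
    ea <- rh * es
    pet_day <- (0.408 * delta * rad +
                  gamma * 900 / (tmean + 273) * wind * (es - ea)) /
      (delta + gamma * (1 + 0.34 * wind))
  }
  pmax(pet_day, 0) * 365 * scale
}

#' Water-holding capacity from soil texture
#'
#' Pedotransfer rule mapping texture to plant-available water-holding
#' capacity: a linear function of clay and silt percent giving mm of water
#' per cm of soil, multiplied by the sampling depth. Coefficients are
#' configuration, not physics: the defaults give 1--3 mm cm^-1 over common
#' textures.
#'
#' @param clay,silt Texture fractions in percent.
#' @param depth_cm Soil depth considered (cm, > 0).
#' @param coef Named coefficients `intercept`, `clay`, `silt` of the
#'   mm-per-cm rule.
#' @return Water-holding capacity (mm) over the given depth.
#' @export
water_holding_capacity <- function(clay, silt, depth_cm,
                                   coef = c(intercept = 0.9, clay = 0.022,
                                            silt = 0.028)) {
  check_num(clay, "clay", lower = 0, upper = 100)
  check_num(silt, "silt", lower = 0, upper = 100)
  check_num(depth_cm, "depth_cm", lower = 0, strict = TRUE, upper = Inf)
  per_cm <- coef[["intercept"]] + coef[["clay"]] * clay +
    coef[["silt"]] * silt
  per_cm * depth_cm
}

#' Single-bucket annual soil water balance
#'
#' Updates a single soil water store year by year: water available for
#' evapotranspiration is the carried-over store plus the year's
#' precipitation; actual ET is the smaller of that and the potential ET;
#' the remainder refills the store up to the water-holding capacity and any
#' excess drains. Water is conserved at every step
#' (`store change = precip - actual ET - drainage`).
#'
#' @param precip Annual precipitation series (mm, >= 0).
#' @param pet Annual potential evapotranspiration series (mm), same length.
#' @param whc Water-holding capacity of the store (mm, > 0).
#' @param store0 Initial store (mm); defaults to a full store.
#' @return A tibble with one row per year: `precip`, `pet`, `aet`,
#'   `drainage`, `store` and the saturation fraction `saturation`
#'   (= store / whc, in \[0, 1\]).
#' @examples
#' water_balance(precip = rep(700, 5), pet = rep(550, 5), whc = 120)
#' @export
water_balance <- function(precip, pet, whc, store0 = whc) {
  if (!is.numeric(whc) || length(whc) != 1 || whc <= 0) {
    stop("whc must be a single positive number", call. = FALSE)
  }
  if (length(precip) != length(pet)) {
    stop("precip and pet series must be aligned (same length)",
         call. = FALSE)
  }
  check_num(precip, "precip", lower = 0)
  check_num(pet, "pet", lower = 0)
  n <- length(precip)
  store <- aet <- drainage <- numeric(n)
  s <- min(max(store0, 0), whc)
  for (i in seq_len(n)) {
    available <- s + precip[i]
    aet[i] <- min(pet[i], available)
    left <- available - aet[i]
    drainage[i] <- max(0, left - whc)
    # clamp roundoff from the subtraction so saturation stays in [0, 1]
    s <- min(max(left - drainage[i], 0), whc)
    store[i] <- s
  }
  tibble::tibble(
    precip = precip, pet = pet, aet = aet, drainage = drainage,
    store = store, saturation = store / whc
  )
}

#' Per-site climate scalars from annual weather
#'
#' Builds the full climate reduction table for a network of sites:
#' temperature response from annual mean temperature, PET and bucket water
#' balance from precipitation and texture, moisture response from the
#' saturation fraction, the multiplicative raw scalar
#' `re_raw = re_temp * r_moist`, and the normalized scalar `re_norm` obtained
#' by dividing by the grand mean of the per-site mean `re_raw` across sites
#' (so the across-site mean of the per-site mean `re_norm` is exactly 1).
#'
#' @param weather A data frame with columns `site_id`, `year`, `tmean_c`,
#'   `precip_mm` and optionally `rad`, `rh`, `wind`.
#' @param sites A data frame with columns `site_id`, `clay`, `silt`,
#'   `depth_cm`.
#' @param pet_scale Scaling term applied to PET. Default 0.9.
#' @param ... Further arguments passed to [temperature_response()] and
#'   [moisture_response()].
#' @return A tibble with columns `site_id`, `year`, `re_temp`, `r_moist`,
#'   `re_raw`, `re_norm`.
#' @seealso [site_re()] for the per-site summary used in calibration and
#'   projection.
#' @export
climate_scalars <- function(weather, sites, pet_scale = 0.9, ...) {
  req <- c("site_id", "year", "tmean_c", "precip_mm")
  if (!all(req %in% names(weather))) {
    stop("weather must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  has_pm <- all(c("rad", "rh", "wind") %in% names(weather))
  out <- weather |>
    dplyr::inner_join(
      dplyr::select(sites, "site_id", "clay", "silt", "depth_cm"),
      by = "site_id"
    ) |>
    dplyr::arrange(.data$site_id, .data$year) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(d, key) {
      pet <- if (has_pm) {
        potential_evapotranspiration(d$tmean_c, d$rad, d$rh, d$wind,
                                     scale = pet_scale)
      } else {
        suppressWarnings(
          potential_evapotranspiration(d$tmean_c, scale = pet_scale)
        )
      }
      whc <- water_holding_capacity(d$clay[1], d$silt[1], d$depth_cm[1])
      wb <- water_balance(d$precip_mm, pet, whc)
      tibble::tibble(
        year = d$year,
        re_temp = temperature_response(d$tmean_c, ...),
        r_moist = moisture_response(wb$saturation),
        re_raw = NA_real_
      ) |>
        dplyr::mutate(re_raw = .data$re_temp * .data$r_moist)
    }) |>
    dplyr::ungroup()
  site_means <- out |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(m = mean(.data$re_raw), .groups = "drop")
  grand <- mean(site_means$m)
  if (!is.finite(grand) || grand <= 0) {
    stop("cannot normalize: all re_raw values are zero", call. = FALSE)
  }
  dplyr::mutate(out, re_norm = .data$re_raw / grand)
}

#' Per-site normalized climate scalar
#'
#' Averages the normalized climate scalar over years for each site. These
#' per-site means have cross-site mean 1 and are the constant `re` used in
#' calibration and future projections.
#'
#' @param climate A tibble from [climate_scalars()].
#' @return A tibble with columns `site_id`, `re_norm`.
#' @export
site_re <- function(climate) {
  climate |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(re_norm = mean(.data$re_norm), .groups = "drop")
}
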