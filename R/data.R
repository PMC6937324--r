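# Light container bundling everything one calibration needs.

#' Bundle sites, observations and climate into a calibration dataset
#'
#' @param sites Site table: one row per site with at least `site_id`, `css`
#'   (initial/steady-state SOC stock, Mg C ha^-1) and `clay` (percent).
#' @param observations Observation table: `site_id`, `time_y` (years since
#'   the experiment start), `soc_stock` (Mg C ha^-1), `sd` (replicate
#'   standard deviation, Mg C ha^-1), and optionally `plant_fraction`,
#'   `plant_sd`.
#' @param climate Optional per-site-year climate table from
#'   [climate_scalars()].
#' @param re Optional per-site climate scalar table (`site_id`, `re_norm`);
#'   derived from `climate` when absent, or a neutral 1 when neither is
#'   given.
#' @return An object of class `qm_data`: a list with components `sites`,
#'   `observations`, `climate`, `re`.
#' @export
qm_data <- function(sites, observations, climate = NULL, re = NULL) {
  need_s <- c("site_id", "css", "clay")
  if (!all(need_s %in% names(sites))) {
    stop("sites must have columns ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  need_o <- c("site_id", "time_y", "soc_stock", "sd")
  if (!all(need_o %in% names(observations))) {
    stop("observations must have columns ", paste(need_o, collapse = ", "),
         call. = FALSE)
  }
  if (any(observations$sd <= 0)) {
    stop("observation sd must be positive", call. = FALSE)
  }
  bad <- observations |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      ok = all(diff(.data$time_y) > 0) && all(.data$time_y >= 0),
      .groups = "drop"
    )
  if (!all(bad$ok)) {
    stop("observation times must be non-negative and strictly increasing ",
         "within each site", call. = FALSE)
  }
  if (is.null(re)) {
    re <- if (!is.null(climate)) {
      site_re(climate)
    } else {
      tibble::tibble(site_id = sites$site_id, re_norm = 1)
    }
  }
  structure(
    list(sites = tibble::as_tibble(sites),
         observations = tibble::as_tibble(observations),
         climate = climate, re = tibble::as_tibble(re)),
    class = "qm_data"
  )
}

#' @export
print.qm_data <- function(x, ...) {
  cat("<qm_data> ", nrow(x$sites), " site(s), ",
      nrow(x$observations), " observations",
      if ("plant_fraction" %in% names(x$observations)) {
        " (with plant fractions)"
      },
      "\n", sep = "")
  print(x$sites, ...)
  invisible(x)
}

#' Interpolate irregular observation series to annual resolution
#'
#' Linear interpolation of each site's series at every integer year between
#' its first and last observation; the original endpoints are preserved
#' exactly (and kept even if non-integer). `soc_stock` and, when present,
#' `plant_fraction` are interpolated; the per-series `sd` columns are carried
#' through unchanged (they describe the series, not a single point).
#'
#' @param observations An observation tibble (see [qm_data()]).
#' @return A tibble with the same columns at annual resolution.
#' @examples
#' obs <- tibble::tibble(site_id = "A", time_y = c(0, 10),
#'                       soc_stock = c(60, 50), sd = 1.5)
#' interpolate_annual(obs)
#' @export
interpolate_annual <- function(observations) {
  observations |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        stop("need at least 2 observations per site to interpolate",
             call. = FALSE)
      }
      t0 <- min(d$time_y); t1 <- max(d$time_y)
      tt <- sort(unique(c(t0, seq(ceiling(t0), floor(t1)), t1)))
      out <- tibble::tibble(
        time_y = tt,
        soc_stock = approx(d$time_y, d$soc_stock, tt)$y,
        sd = mean(d$sd)
      )
      if ("plant_fraction" %in% names(d) && any(!is.na(d$plant_fraction))) {
        keep <- !is.na(d$plant_fraction)
        if (sum(keep) >= 2) {
          rng <- range(d$time_y[keep])
          out$plant_fraction <- ifelse(
            tt >= rng[1] & tt <= rng[2],
            approx(d$time_y[keep], d$plant_fraction[keep], pmin(pmax(tt,
                   rng[1]), rng[2]))$y,
            NA_real_
          )
        } else {
          out$plant_fraction <- NA_real_
        }
        out$plant_sd <- if ("plant_sd" %in% names(d)) {
          mean(d$plant_sd, na.rm = TRUE)
        } else {
          NA_real_
        }
      }
      out
    }) |>
    dplyr::ungroup()
}
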