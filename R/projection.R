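# Long-horizon stock projections and fit reports.

#' Project SOC stocks over long horizons with credible intervals
#'
#' Evaluates the closed-form stock equation at each horizon for every
#' (thinned) post-burn-in posterior draw, using each site's constant mean
#' normalized climate scalar, and summarises the draws by their median and
#' empirical central 95 % interval. Because the model has no inert pool,
#' every draw's trajectory declines strictly at all horizons.
#'
#' @param fit A `qm_fit` object.
#' @param horizons Projection horizons in years (>= 0).
#'   Default `c(300, 1000, 3000)`.
#' @param thin Keep every `thin`-th post-burn-in draw. Default 10.
#' @param conf_level Credible-interval mass. Default 0.95.
#' @param re Optional per-site climate scalar tibble (`site_id`, `re_norm`)
#'   overriding the one stored in the fit's data.
#' @return A tibble with columns `site_id`, `horizon_y`, `median`, `lower`,
#'   `upper` (Mg C ha^-1).
#' @export
project_stocks <- function(fit, horizons = c(300, 1000, 3000), thin = 10,
                           conf_level = 0.95, re = NULL) {
  stopifnot(inherits(fit, "qm_fit"))
  if (any(horizons < 0)) stop("horizons must be >= 0", call. = FALSE)
  post <- posterior_draws(fit)
  post <- post[seq(1, nrow(post), by = thin), ]
  if (nrow(post) < 1) stop("no post-burn-in draws to project",
                           call. = FALSE)
  re_tbl <- if (!is.null(re)) re else fit$data$re
  a <- (1 - conf_level) / 2
  purrr::map_dfr(fit$site_ids, function(id) {
    site <- fit$data$sites[fit$data$sites$site_id == id, ]
    re_i <- re_tbl$re_norm[re_tbl$site_id == id]
    loc <- local_cols(fit, id)
    purrr::map_dfr(horizons, function(h) {
      stocks <- soc_stock(
        h, site$css, post[[loc["q0"]]],
        effective_beta(post[[loc["beta0"]]], site$clay),
        post[[loc["eta11"]]], post[[loc["u0"]]], post[[loc["e0"]]], re_i
      )
      tibble::tibble(
        site_id = id, horizon_y = h,
        median = median(stocks),
        lower = unname(quantile(stocks, a)),
        upper = unname(quantile(stocks, 1 - a))
      )
    })
  })
}

#' Fit report for one or all sites
#'
#' Summarises how the calibrated chain fits a site's observations: the
#' trajectory of the single best-RMSE parameter set, the envelope (pointwise
#' min/max) of trajectories from all draws within the 95 % quantile of the
#' RMSE distribution, and RMSE statistics (mean, kernel-density mode, and
#' mean RMSE as a percentage of the final observed stock).
#'
#' @param fit A `qm_fit` object.
#' @param sites Site ids to report; default all.
#' @param times Evaluation times (years); default every year over each
#'   site's observed span.
#' @param rmse_quantile Draws with RMSE at or below this quantile form the
#'   envelope. Default 0.95.
#' @param thin Keep every `thin`-th post-burn-in draw for the envelope.
#'   Default 10.
#' @return An object of class `qm_fit_report`: list with `trajectories`
#'   (tibble: `site_id`, `time_y`, `best`, `lower`, `upper`), `stats`
#'   (from [rmse_summary()]) and the observations used.
#' @export
report_fit <- function(fit, sites = NULL, times = NULL,
                       rmse_quantile = 0.95, thin = 10) {
  stopifnot(inherits(fit, "qm_fit"))
  if (is.null(sites)) sites <- fit$site_ids
  post <- posterior_draws(fit)
  post <- post[seq(1, nrow(post), by = thin), ]
  trajectories <- purrr::map_dfr(sites, function(id) {
    site <- fit$data$sites[fit$data$sites$site_id == id, ]
    obs <- fit$data$observations[fit$data$observations$site_id == id, ]
    tt <- if (is.null(times)) seq(0, max(obs$time_y)) else times
    re_i <- fit$data$re$re_norm[fit$data$re$site_id == id]
    loc <- local_cols(fit, id)
    rmse_col <- paste0("rmse_", id)
    traj <- function(row) {
      soc_stock(tt, site$css, row[[loc["q0"]]],
                effective_beta(row[[loc["beta0"]]], site$clay),
                row[[loc["eta11"]]], row[[loc["u0"]]], row[[loc["e0"]]],
                re_i)
    }
    best <- traj(post[which.min(post[[rmse_col]]), ])
    keep <- post[[rmse_col]] <=
      quantile(post[[rmse_col]], rmse_quantile, type = 1)
    env <- vapply(which(keep), function(i) traj(post[i, ]),
                  numeric(length(tt)))
    tibble::tibble(
      site_id = id, time_y = tt, best = best,
      lower = apply(env, 1, min), upper = apply(env, 1, max)
    )
  })
  structure(
    list(trajectories = trajectories,
         stats = rmse_summary(fit),
         observations = fit$data$observations[
           fit$data$observations$site_id %in% sites, ]),
    class = "qm_fit_report"
  )
}

#' @export
print.qm_fit_report <- function(x, ...) {
  cat("<qm_fit_report> ", length(unique(x$trajectories$site_id)),
      " site(s)\n", sep = "")
  print(x$stats, ...)
  invisible(x)
}

# map the generic/local column names for one site
local_cols <- function(fit, id) {
  if (fit$parameterization == "local") {
    c(u0 = "u0", eta11 = "eta11", q0 = paste0("q0_", id),
      e0 = paste0("e0_", id), beta0 = paste0("beta0_", id))
  } else {
    c(u0 = "u0", eta11 = "eta11", q0 = "q0", e0 = "e0", beta0 = "beta0")
  }
}
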