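# broom-style accessors for calibrated fits

#' @export
print.qm_fit <- function(x, ...) {
  cat("<qm_fit> ", x$config$n_chains, " chain(s) x ", x$config$n_iter,
      " iterations (burn-in ", x$config$burn_in, ", thin ", x$config$thin,
      "), ", x$parameterization, " parameterization\n", sep = "")
  cat("parameters: ", paste(x$par_names, collapse = ", "), "\n", sep = "")
  print(glance(x), ...)
  invisible(x)
}

#' Tidy summary of a calibrated fit
#'
#' One row per model parameter with posterior median, mean, central credible
#' interval and Gelman-Rubin R-hat, computed on post-burn-in draws pooled
#' across chains.
#'
#' @param x A `qm_fit` object.
#' @param conf_level Credible-interval mass. Default 0.95.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `median`, `mean`, `conf.low`,
#'   `conf.high`, `rhat`.
#' @export
tidy.qm_fit <- function(x, conf_level = 0.95, ...) {
  post <- posterior_draws(x)
  a <- (1 - conf_level) / 2
  rh <- if (x$config$n_chains >= 2) gelman_rubin(x) else {
    tibble::tibble(parameter = x$par_names, rhat = NA_real_)
  }
  purrr::map_dfr(x$par_names, function(p) {
    v <- post[[p]]
    tibble::tibble(
      parameter = p,
      median = median(v), mean = mean(v),
      conf.low = unname(quantile(v, a)),
      conf.high = unname(quantile(v, 1 - a))
    )
  }) |>
    dplyr::left_join(rh, by = "parameter")
}

#' One-row summary of a calibrated fit
#'
#' @param x A `qm_fit` object.
#' @param ... Unused.
#' @return A tibble with the chain configuration, maximum R-hat over
#'   parameters, mean posterior log likelihood, and the mean (across sites
#'   and draws) posterior SOC RMSE.
#' @export
glance.qm_fit <- function(x, ...) {
  post <- posterior_draws(x)
  rmse_cols <- paste0("rmse_", x$site_ids)
  max_rhat <- if (x$config$n_chains >= 2) max(gelman_rubin(x)$rhat) else {
    NA_real_
  }
  tibble::tibble(
    n_chains = x$config$n_chains,
    n_iter = x$config$n_iter,
    burn_in = x$config$burn_in,
    n_draws = nrow(post),
    max_rhat = max_rhat,
    mean_log_lik = mean(post$log_lik),
    mean_rmse = mean(colMeans(post[rmse_cols]))
  )
}

#' Posterior RMSE summary per site
#'
#' Mean and mode (kernel-density peak) of the posterior RMSE distribution of
#' each site, plus the RMSE as a percentage of the site's final observed
#' stock.
#'
#' @param fit A `qm_fit` object.
#' @return A tibble with columns `site_id`, `rmse_mean`, `rmse_mode`,
#'   `rmse_pct_final`.
#' @export
rmse_summary <- function(fit) {
  post <- posterior_draws(fit)
  purrr::map_dfr(fit$site_ids, function(id) {
    v <- post[[paste0("rmse_", id)]]
    dens <- density(v)
    obs <- fit$data$observations
    final <- obs$soc_stock[obs$site_id == id]
    final <- final[length(final)]
    tibble::tibble(
      site_id = id,
      rmse_mean = mean(v),
      rmse_mode = dens$x[which.max(dens$y)],
      rmse_pct_final = mean(v) / final * 100
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
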