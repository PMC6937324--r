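# Hornberger-Spear-Young (HSY) generalized sensitivity analysis.
#
# Parameter sets from a calibrated chain are split into behavioral and
# non-behavioral bins at a performance (RMSE) quantile; the Kolmogorov-
# Smirnov distance between the two bins' marginal distributions of a
# parameter measures how strongly that parameter controls model performance.

#' Split a chain into behavioral and non-behavioral parameter sets
#'
#' Orders the elements of a chain by their RMSE and declares the best
#' `ceiling(quantile * n)` elements behavioral; the threshold is the
#' empirical lower-interpolation (type 1) order statistic at `quantile`.
#' Ties at the threshold are broken by including equal-RMSE elements in
#' chain order up to the exact count, so the behavioral bin always has
#' `ceiling(quantile * n)` elements.
#'
#' @param draws A draws tibble (e.g. from [posterior_draws()]) or a
#'   `qm_fit` object.
#' @param rmse Name of the RMSE column to threshold on (for a multi-site
#'   fit, one of the `rmse_<site>` columns).
#' @param quantile Behavioral quantile in (0, 1). Default 0.05.
#' @return An object of class `qm_hsy`: list with `elements` (the draws
#'   tibble plus a logical `behavioral` column), `threshold` (Mg C ha^-1),
#'   `rmse` and `quantile`.
#' @export
hsy_partition <- function(draws, rmse = "rmse", quantile = 0.05) {
  if (inherits(draws, "qm_fit")) draws <- posterior_draws(draws)
  if (quantile <= 0 || quantile >= 1) {
    stop("quantile must be strictly inside (0, 1)", call. = FALSE)
  }
  if (!rmse %in% names(draws)) {
    stop("no column named '", rmse, "' in draws", call. = FALSE)
  }
  n <- nrow(draws)
  if (n == 0) stop("empty chain", call. = FALSE)
  k <- ceiling(quantile * n)
  ord <- order(draws[[rmse]])
  behavioral <- logical(n)
  behavioral[ord[seq_len(k)]] <- TRUE
  threshold <- unname(stats::quantile(draws[[rmse]], quantile, type = 1))
  structure(
    list(
      elements = dplyr::mutate(draws, behavioral = behavioral),
      threshold = threshold,
      rmse = rmse,
      quantile = quantile
    ),
    class = "qm_hsy"
  )
}

#' @export
print.qm_hsy <- function(x, ...) {
  cat("<qm_hsy> ", sum(x$elements$behavioral), " behavioral / ",
      nrow(x$elements), " elements; RMSE threshold ",
      signif(x$threshold, 4), " (", x$rmse, ", quantile ", x$quantile,
      ")\n", sep = "")
  invisible(x)
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' Supremum distance between the empirical CDFs of `x` and `y`; in \[0, 1\]
#' and invariant under strictly monotone transforms of the values.
#'
#' @param x,y Numeric samples (non-empty).
#' @return The KS distance.
#' @export
ks_distance <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pts <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pts)
  fy <- stats::ecdf(y)(pts)
  max(abs(fx - fy))
}

#' Per-parameter KS sensitivity of an HSY partition
#'
#' Computes the KS distance between the behavioral and non-behavioral bins'
#' marginal distributions for each requested parameter.
#'
#' @param partition A `qm_hsy` object from [hsy_partition()].
#' @param parameters Character vector of parameter columns; defaults to all
#'   numeric columns except bookkeeping ones.
#' @return A tibble with columns `parameter`, `ks`.
#' @export
ks_sensitivity <- function(partition, parameters = NULL) {
  stopifnot(inherits(partition, "qm_hsy"))
  el <- partition$elements
  if (sum(el$behavioral) == 0 || sum(!el$behavioral) == 0) {
    stop("both HSY bins must be non-empty", call. = FALSE)
  }
  if (is.null(parameters)) {
    skip <- c("chain", "iteration", "log_prior", "log_lik", "log_post",
              "behavioral")
    parameters <- setdiff(names(el)[vapply(el, is.numeric, TRUE)], skip)
    parameters <- parameters[!startsWith(parameters, "rmse")]
  }
  purrr::map_dfr(parameters, function(p) {
    tibble::tibble(
      parameter = p,
      ks = ks_distance(el[[p]][el$behavioral], el[[p]][!el$behavioral])
    )
  })
}

#' Average KS sensitivities across sites and rank parameters
#'
#' Takes per-site KS tables (a list of tibbles from [ks_sensitivity()], or a
#' single long tibble with a `site_id` column) and returns the arithmetic
#' mean KS distance per parameter, sorted descending.
#'
#' @param ks_tables List of per-site KS tibbles, or one long tibble with
#'   columns `site_id`, `parameter`, `ks`.
#' @return A tibble with columns `parameter`, `mean_ks`, `rank`.
#' @export
rank_parameters <- function(ks_tables) {
  long <- if (is.data.frame(ks_tables)) ks_tables else {
    dplyr::bind_rows(ks_tables, .id = "site_id")
  }
  long |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean_ks = mean(.data$ks), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_ks)) |>
    dplyr::mutate(rank = dplyr::row_number())
}
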