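#' Posterior-predictive summary for one country and wave
#'
#' For each retained draw the trajectory value
#' \eqn{\mu = \alpha + f(u) + g_i(u)} is evaluated at the wave's scaled time;
#' with `include_noise` an observation-level Gaussian error at the draw's
#' error precision is added. The wave may be unobserved (e.g. the forecast
#' wave `"2021/22"`).
#'
#' @param draws a `dp_draws` object from [run_mcmc()].
#' @param country country code present in the fit.
#' @param wave_label wave label resolvable via the fit's time mapping.
#' @param include_noise logical; if `TRUE` the summary describes a new
#'   observation rather than the latent trajectory. Default `FALSE`: reported
#'   point estimates are posterior means of the smooth trajectory.
#' @return one-row data.frame: `country`, `wave`, `mean` (clamped to
#'   [0, 100]), `sd`, `lower`, `upper` (central 95% interval).
#' @export
posterior_predictive <- function(draws, country, wave_label,
                                 include_noise = FALSE) {
  stopifnot(inherits(draws, "dp_draws"))
  i <- match(country, draws$countries)
  if (is.na(i)) stop("unknown country: ", country)
  dr <- design_row(draws$config, wave_label)
  mu <- draws$alpha + as.vector(draws$beta %*% dr$fixed) +
    as.vector(dr$random %*% draws$b[i, , ])
  if (include_noise)
    mu <- mu + stats::rnorm(length(mu), 0, 1 / sqrt(draws$tau_eps))
  qs <- stats::quantile(mu, c(0.025, 0.975), names = FALSE)
  clamp <- function(x) pmin(pmax(x, 0), 100)
  data.frame(country = country, wave = wave_label,
             mean = clamp(mean(mu)), sd = stats::sd(mu),
             lower = clamp(qs[1L]), upper = clamp(qs[2L]))
}

#' Mask one wave of a panel
#'
#' Returns the panel with every cell of `wave_label` set to missing, as used
#' for hold-out validation. Countries observed only at that wave would be
#' left without data and trigger an error.
#'
#' @param panel a [prevalence_panel()].
#' @param wave_label wave to mask.
#' @return a [prevalence_panel()] with the wave blanked.
#' @export
mask_wave <- function(panel, wave_label) {
  stopifnot(inherits(panel, "prevalence_panel"))
  if (!wave_label %in% panel$waves) stop("unknown wave: ", wave_label)
  vals <- panel$values
  vals[, wave_label] <- NA_real_
  prevalence_panel(vals, gender = panel$gender)
}

#' Summary statistics of absolute errors
#'
#' Mean, median (midpoint convention for even lengths), sample standard
#' deviation (n - 1 denominator), minimum and maximum, each rounded to two
#' decimals.
#'
#' @param aes non-empty numeric vector of absolute errors.
#' @return named numeric vector `mean`, `median`, `sd`, `min`, `max`.
#' @export
ae_summary <- function(aes) {
  if (length(aes) == 0L) stop("empty vector of absolute errors")
  round(c(mean = mean(aes), median = stats::median(aes),
          sd = if (length(aes) > 1L) stats::sd(aes) else 0,
          min = min(aes), max = max(aes)), 2L)
}

#' Model assessment against one survey wave
#'
#' Compares model estimates of one wave's prevalences with the observed
#' values for every country that reported that wave, and summarises the
#' per-country absolute errors |estimated - observed|.
#'
#' Two assessment modes are available. `"estimate"` (the default) fits the
#' model on the full panel and evaluates each country's posterior trajectory
#' at the assessment wave, so the errors measure how far the smooth
#' cluster-level trends sit from the observations they were fitted to —
#' the published-table convention this package reproduces. `"masked"` refits
#' with every cell of the assessment wave blanked first, making the errors
#' genuine out-of-sample forecast errors; they are substantially larger,
#' since the polynomial trends must then extrapolate beyond the last
#' observed wave.
#'
#' @param panel a [prevalence_panel()] including the assessment wave.
#' @param config a [model_config()] for the fit.
#' @param holdout_wave wave label to assess (e.g. `"2017/18"`).
#' @param method `"estimate"` (in-sample trajectory values from the full
#'   fit) or `"masked"` (wave blanked before fitting).
#' @return An object of class `ae_report`: list with `table` (data.frame
#'   `country`, `observed`, `predicted`, `ae`, `cluster`, ordered as in the
#'   panel), `summary` (from [ae_summary()] on the rounded per-country AEs),
#'   `holdout_wave`, `method`, `gender`, `partition` (the fit's point
#'   partition) and `draws` (the fit's posterior draws).
#' @export
holdout_validation <- function(panel, config = model_config(),
                               holdout_wave = "2017/18",
                               method = c("estimate", "masked")) {
  method <- match.arg(method)
  if (!holdout_wave %in% panel$waves) stop("unknown wave: ", holdout_wave)
  observed <- panel$values[, holdout_wave]
  keep <- which(!is.na(observed))
  if (length(keep) == 0L)
    stop("no country observes the hold-out wave ", holdout_wave)
  fit_panel <- if (method == "masked") mask_wave(panel, holdout_wave) else panel
  draws <- run_mcmc(fit_panel, config)
  part <- point_partition(draws)
  pred <- vapply(panel$countries[keep], function(cc)
    posterior_predictive(draws, cc, holdout_wave)$mean, numeric(1))
  tab <- data.frame(country = panel$countries[keep],
                    observed = unname(observed[keep]),
                    predicted = round(unname(pred), 2L),
                    ae = round(abs(unname(pred) - unname(observed[keep])), 2L),
                    cluster = unname(part$labels[panel$countries[keep]]),
                    row.names = NULL)
  structure(list(table = tab, summary = ae_summary(tab$ae),
                 holdout_wave = holdout_wave, method = method,
                 gender = panel$gender, partition = part, draws = draws),
            class = "ae_report")
}

#' @export
print.ae_report <- function(x, ...) {
  cat(sprintf("Model assessment, wave %s (%s, %s): %d countries\n",
              x$holdout_wave, x$gender, x$method, nrow(x$table)))
  print(x$table, row.names = FALSE)
  cat(sprintf("overall AE: mean %.2f, median %.2f, sd %.2f, min %.2f, max %.2f\n",
              x$summary["mean"], x$summary["median"], x$summary["sd"],
              x$summary["min"], x$summary["max"]))
  invisible(x)
}

#' Forecast an unobserved wave for every country
#'
#' Posterior-predictive trajectory means (and 95% intervals) at a future
#' wave, from draws fitted on the full panel.
#'
#' @param draws a `dp_draws` object fitted on the full (unmasked) panel.
#' @param wave_label wave to forecast; default the next survey wave
#'   `"2021/22"`.
#' @return data.frame with one row per country: `country`, `wave`, `mean`
#'   (rounded to 2 decimals), `sd`, `lower`, `upper`.
#' @export
forecast_wave <- function(draws, wave_label = "2021/22") {
  out <- do.call(rbind, lapply(draws$countries, function(cc)
    posterior_predictive(draws, cc, wave_label)))
  out$mean <- round(out$mean, 2L)
  rownames(out) <- NULL
  out
}
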