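#' Read and write model configuration files
#'
#' Configurations are stored as flat JSON key/value files mirroring the
#' arguments of [model_config()]; the time mapping is stored as
#' `center_year` / `scale_years`. Unknown keys are an error, so typos do not
#' silently fall back to defaults.
#'
#' @param path path to a JSON config file.
#' @param overrides named list merged over the file's values (used for
#'   command-line `--iters`-style overrides).
#' @return a [model_config()].
#' @export
read_model_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else jsonlite::read_json(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  tm <- time_mapping(
    center_year = if (is.null(vals$center_year)) 2002 else vals$center_year,
    scale_years = if (is.null(vals$scale_years)) 16 else vals$scale_years)
  vals$center_year <- vals$scale_years <- NULL
  known <- setdiff(names(formals(model_config)), "time_mapping")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(model_config, c(vals, list(time_mapping = tm)))
}

config_as_list <- function(config) {
  c(config[setdiff(names(config), "time_mapping")],
    list(center_year = config$time_mapping$center_year,
         scale_years = config$time_mapping$scale_years))
}

write_manifest <- function(out_dir, command, panel_path, config, outputs) {
  manifest <- list(
    command = command,
    panel = panel_path,
    panel_md5 = unname(tools::md5sum(panel_path)),
    config = config_as_list(config),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  stopifnot(all(file.exists(file.path(out_dir, outputs))))
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)  # manifest appears atomically, after its outputs
  invisible(path)
}

#' Fit, cluster and summarise one gender's panel
#'
#' End-to-end fit stage: runs the Gibbs sampler on the full panel, then
#' writes the retained draws, the posterior similarity matrix, the point
#' partition, per-country fitted trajectories at every observed wave, and a
#' run manifest into `out_dir`.
#'
#' @param panel_path CSV panel path (layout of [load_prevalence_table()]).
#' @param gender `"boys"` or `"girls"`.
#' @param config a [model_config()].
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with `draws`, `partition` and the output paths.
#' @export
run_fit <- function(panel_path, gender, config = model_config(),
                    out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- load_prevalence_table(panel_path, gender)
  draws <- run_mcmc(panel, config)
  part <- point_partition(draws)
  message(sprintf("posterior K distribution: %s",
                  paste(sprintf("K=%s:%.2f", names(k_distribution(draws)),
                                k_distribution(draws)), collapse = " ")))
  fitted <- do.call(rbind, lapply(panel$waves, function(w)
    do.call(rbind, lapply(panel$countries, function(cc)
      posterior_predictive(draws, cc, w)))))
  write_draws(draws, file.path(out_dir, "draws.csv"))
  write_partition(part, file.path(out_dir, "similarity.csv"),
                  file.path(out_dir, "partition.csv"))
  utils::write.csv(fitted, file.path(out_dir, "fitted.csv"), row.names = FALSE)
  write_manifest(out_dir, "fit", panel_path, config,
                 c("draws.csv", "similarity.csv", "partition.csv", "fitted.csv"))
  invisible(list(draws = draws, partition = part, out_dir = out_dir))
}

#' Hold-out validation stage
#'
#' Masks `holdout_wave`, refits, and writes the per-country absolute-error
#' table (country, observed, predicted, AE, cluster) with the overall
#' summary row appended, plus a manifest.
#'
#' @inheritParams run_fit
#' @param holdout_wave wave label to assess.
#' @param method assessment mode passed to [holdout_validation()].
#' @return invisibly, the `ae_report` and output paths.
#' @export
run_validate <- function(panel_path, gender, config = model_config(),
                         holdout_wave = "2017/18", out_dir = ".",
                         method = "estimate") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- load_prevalence_table(panel_path, gender)
  report <- holdout_validation(panel, config, holdout_wave, method)
  tab <- report$table
  summary_row <- data.frame(country = "Overall", observed = NA_real_,
                            predicted = NA_real_, ae = report$summary["mean"],
                            cluster = NA_integer_)
  out <- file.path(out_dir, "ae_report.csv")
  utils::write.csv(rbind(tab, summary_row), out, row.names = FALSE, na = "")
  utils::write.csv(data.frame(statistic = names(report$summary),
                              value = unname(report$summary)),
                   file.path(out_dir, "ae_summary.csv"), row.names = FALSE)
  write_manifest(out_dir, "validate", panel_path, config,
                 c("ae_report.csv", "ae_summary.csv"))
  invisible(list(report = report, out_dir = out_dir))
}

#' Forecast stage
#'
#' Fits on the full panel and writes per-country predictive means and 95%
#' intervals for a future wave (default `"2021/22"`), plus a manifest.
#'
#' @inheritParams run_fit
#' @param wave_label wave to forecast.
#' @return invisibly, the forecast table and output paths.
#' @export
run_forecast <- function(panel_path, gender, config = model_config(),
                         wave_label = "2021/22", out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- load_prevalence_table(panel_path, gender)
  draws <- run_mcmc(panel, config)
  fc <- forecast_wave(draws, wave_label)
  utils::write.csv(fc, file.path(out_dir, "forecast.csv"), row.names = FALSE)
  write_manifest(out_dir, "forecast", panel_path, config, "forecast.csv")
  invisible(list(forecast = fc, draws = draws, out_dir = out_dir))
}

#' Simulation stage
#'
#' Generates a synthetic panel with known truth and writes the panel CSV and
#' a JSON sidecar with the generating parameters.
#'
#' @param out_dir output directory.
#' @param ... passed to [generate_panel()].
#' @return invisibly, the generated panel/truth and output paths.
#' @export
run_simulate <- function(out_dir = ".", ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_panel(...)
  write_prevalence_table(gen$panel, file.path(out_dir, "panel.csv"))
  truth <- gen$truth
  truth$mask <- NULL  # recoverable from the panel's missingness pattern
  truth$trajectory <- NULL
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = gen$panel, truth = gen$truth, out_dir = out_dir))
}
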