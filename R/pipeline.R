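#' Configuration for a pipeline run
#'
#' Collects inputs and policy choices for [run_forecast()],
#' [run_hindcast()] and [run_attribution()].  Inputs may be file paths (the
#' package's CSV readers are used) or in-memory objects; worked scalar
#' inputs (a published N, emissions value or previous annual mean) may be
#' injected directly, which is how printed forecasts are reproduced.
#'
#' Exactly one seasonal-factor source must be given: `seasonal_factors`
#' (injected values, e.g. a published adjustment table) or
#' `seasonal_reference_years` (computed from the CO2 record).
#'
#' @param target_year forecast year i.
#' @param co2 ppm [monthly_series()] or path for [read_monthly_csv()].
#' @param sst_obs,sst_fcst [ensemble_series()] or paths for
#'   [read_ensemble_csv()].
#' @param emissions [emissions_series()] or path for [read_emissions_csv()].
#' @param split `c(year, month)` where forecast SST coverage starts.
#' @param calibration_years target years i used to calibrate (default
#'   `1960:2014`, the rows available to a 1959-2014 record after increment
#'   differencing and the one-year emissions lag).
#' @param excluded_years years removed from calibration (e.g. post-eruption
#'   years for sensitivity runs); default none.
#' @param alpha optional length-3 coefficient override: bypasses
#'   calibration, recorded in provenance.
#' @param residual_sd residual spread accompanying an `alpha` override.
#' @param fixed_two_sd optional fixed 2-s.d. half-width in ppm (otherwise
#'   2 x residual sd of the calibration).
#' @param seasonal_factors 12 injected monthly factors (ppm) or a
#'   [seasonal_cycle()].
#' @param seasonal_reference_years years from which to compute the factors.
#' @param nino_value optional injected windowed N (degC).
#' @param nino_two_sd 2-s.d. uncertainty accompanying `nino_value`.
#' @param emissions_value optional injected eps (GtC, year i-1).
#' @param prev_annual_mean optional injected annual mean of year i-1 (ppm).
#' @param trend,trend_years recent concentration trend (ppm/yr) and horizon
#'   for the trend-extrapolation attribution estimate.
#' @param report_month month highlighted by [run_attribution()] (default 9,
#'   September, the annual minimum).
#' @param gap_policy annual-mean gap policy (see [annual_mean()]).
#' @param outdir optional directory for report files and provenance.
#' @param seed RNG seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(target_year,
                       co2 = NULL, sst_obs = NULL, sst_fcst = NULL,
                       emissions = NULL, split = NULL,
                       calibration_years = 1960:2014,
                       excluded_years = integer(),
                       alpha = NULL, residual_sd = NA_real_,
                       fixed_two_sd = NULL,
                       seasonal_factors = NULL,
                       seasonal_reference_years = NULL,
                       nino_value = NULL, nino_two_sd = NA_real_,
                       emissions_value = NULL,
                       prev_annual_mean = NULL,
                       trend = NULL, trend_years = 1L,
                       report_month = 9L,
                       gap_policy = "strict",
                       outdir = NULL, seed = 1L) {
  if (is.null(seasonal_factors) == is.null(seasonal_reference_years))
    stop("give exactly one of seasonal_factors or seasonal_reference_years")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

load_input <- function(x, reader, ...) {
  if (is.null(x) || !is.character(x)) x else reader(x, ...)
}

resolve_inputs <- function(config) {
  config$input_paths <- Filter(is.character,
                               config[c("co2", "sst_obs", "sst_fcst",
                                        "emissions")])
  config$co2 <- load_input(config$co2, read_monthly_csv, units = "ppm")
  config$sst_obs <- load_input(config$sst_obs, read_ensemble_csv,
                               source = "observed")
  config$sst_fcst <- load_input(config$sst_fcst, read_ensemble_csv,
                                source = "forecast")
  config$emissions <- load_input(config$emissions, read_emissions_csv)
  config
}

resolve_cycle <- function(config) {
  if (!is.null(config$seasonal_factors)) {
    if (inherits(config$seasonal_factors, "seasonal_cycle"))
      config$seasonal_factors
    else seasonal_cycle(config$seasonal_factors)
  } else {
    if (is.null(config$co2)) stop("seasonal_reference_years needs a CO2 record")
    seasonal_factors(config$co2, config$seasonal_reference_years)
  }
}

resolve_model <- function(config, stage) {
  if (!is.null(config$alpha)) {
    a <- config$alpha
    return(increment_model(a[1], a[2], a[3], config$residual_sd))
  }
  for (nm in c("co2", "emissions"))
    if (is.null(config[[nm]]))
      stop(sprintf("%s: calibration requires '%s' input", stage, nm))
  if (is.null(config$sst_obs))
    stop(sprintf("%s: calibration requires 'sst_obs' input", stage))
  yrs <- setdiff(config$calibration_years, config$excluded_years)
  centrals <- vapply(yrs, function(y) {
    w <- vapply(config$sst_obs$members, function(m)
      tryCatch(window_mean(m, y), error = function(e) NA_real_), numeric(1))
    mean(w)
  }, numeric(1))
  rows <- build_design_rows(config$co2, stats::setNames(centrals, yrs),
                            config$emissions, yrs, config$gap_policy)
  fit_increment_model(rows)
}

resolve_nino <- function(config, stage, use_forecast) {
  if (!is.null(config$nino_value))
    return(list(central = config$nino_value, two_sd = config$nino_two_sd))
  if (is.null(config$sst_obs))
    stop(sprintf("%s: need nino_value or sst_obs", stage))
  if (use_forecast) {
    if (is.null(config$sst_fcst) || is.null(config$split))
      stop(sprintf("%s: need sst_fcst and split for a forecast N", stage))
    combine_obs_forecast(config$sst_obs, config$sst_fcst, config$split,
                         config$target_year)
  } else {
    windowed_nino(config$target_year,
                  vapply(config$sst_obs$members, window_mean, numeric(1),
                         target_year = config$target_year))
  }
}

resolve_epsilon <- function(config, stage) {
  if (!is.null(config$emissions_value)) return(config$emissions_value)
  if (is.null(config$emissions))
    stop(sprintf("%s: need emissions_value or emissions table", stage))
  e <- emissions_for(config$emissions, config$target_year - 1L)
  if (is.na(e))
    stop(sprintf("%s: emissions table lacks year %d", stage,
                 config$target_year - 1L))
  e
}

resolve_prev_mean <- function(config, stage) {
  if (!is.null(config$prev_annual_mean)) return(config$prev_annual_mean)
  if (is.null(config$co2))
    stop(sprintf("%s: need prev_annual_mean or CO2 record", stage))
  annual_mean(config$co2, config$target_year - 1L, config$gap_policy)
}

write_provenance <- function(config, outdir, stage) {
  path <- file.path(outdir, paste0(stage, "_provenance.txt"))
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("stage: %s\npackage: co2cast %s\nseed: %d\ndate: %s\n",
              stage, as.character(utils::packageVersion("co2cast")),
              config$seed, format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file = con)
  for (nm in names(config$input_paths)) {
    x <- config$input_paths[[nm]]
    cat(sprintf("input %s: %s md5=%s\n", nm, x, unname(tools::md5sum(x))),
        file = con)
  }
  scalars <- config[vapply(config, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  for (nm in names(scalars))
    cat(sprintf("config %s: %s\n", nm,
                paste(format(scalars[[nm]]), collapse = " ")), file = con)
  if (!is.null(config$alpha))
    cat("note: coefficient override in effect; calibration bypassed\n",
        file = con)
  invisible(path)
}

#' Run the end-to-end CO2 forecast pipeline
#'
#' Chains the stages of a pre-season forecast: windowed Nino index from the
#' observed-plus-forecast SST ensembles (or an injected value), previous-year
#' emissions, increment prediction, and downscaling to annual and monthly
#' concentrations via the seasonal factors.
#'
#' @param config a [run_config()].
#' @return A [forecast_concentrations()] result, with attributes `model`
#'   and `nino` attached; report files and a provenance record are written
#'   when `outdir` is set.
#' @export
run_forecast <- function(config) {
  stopifnot(inherits(config, "run_config"))
  config <- resolve_inputs(config)
  model <- resolve_model(config, "forecast")
  nino <- resolve_nino(config, "forecast", use_forecast = TRUE)
  eps <- resolve_epsilon(config, "forecast")
  prev <- resolve_prev_mean(config, "forecast")
  cycle <- resolve_cycle(config)
  pred <- predict_increment(model, nino$central, eps,
                            two_sd = config$fixed_two_sd)
  fc <- forecast_concentrations(prev, pred, cycle,
                                target_year = config$target_year)
  attr(fc, "model") <- model
  attr(fc, "nino") <- nino
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(month = 1:12,
                                forecast_ppm = round(fc$monthly_means, 2)),
                     file.path(config$outdir, "forecast_monthly.csv"),
                     row.names = FALSE, quote = FALSE)
    write_provenance(config, config$outdir, "forecast")
  }
  fc
}

#' Run a hindcast with observed inputs
#'
#' Identical arithmetic to [run_forecast()] but the windowed Nino index is
#' taken from observed SST realizations alone (no forecast splice), the
#' retrospective check of method robustness.
#'
#' @param config a [run_config()].
#' @return A [forecast_concentrations()] result (attributes as in
#'   [run_forecast()]).
#' @export
run_hindcast <- function(config) {
  stopifnot(inherits(config, "run_config"))
  config <- resolve_inputs(config)
  model <- resolve_model(config, "hindcast")
  nino <- resolve_nino(config, "hindcast", use_forecast = FALSE)
  eps <- resolve_epsilon(config, "hindcast")
  prev <- resolve_prev_mean(config, "hindcast")
  cycle <- resolve_cycle(config)
  pred <- predict_increment(model, nino$central, eps,
                            two_sd = config$fixed_two_sd)
  fc <- forecast_concentrations(prev, pred, cycle,
                                target_year = config$target_year)
  attr(fc, "model") <- model
  attr(fc, "nino") <- nino
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(month = 1:12,
                                hindcast_ppm = round(fc$monthly_means, 2)),
                     file.path(config$outdir, "hindcast_monthly.csv"),
                     row.names = FALSE, quote = FALSE)
    write_provenance(config, config$outdir, "hindcast")
  }
  fc
}

#' Run the counterfactual attribution pipeline
#'
#' Computes the with-El-Nino increment, the N = 0 counterfactual, the
#' contribution decomposition, the no-El-Nino concentration for the report
#' month, and (when a trend is configured) the alternative
#' trend-extrapolation estimate for that month.
#'
#' @param config a [run_config()]; `trend` enables the extrapolation
#'   estimate, which uses the observed report-month value of year i-1 as
#'   its baseline (requires the CO2 record or an injected
#'   `prev_month_value` attribute via `trend_baseline`).
#' @param trend_baseline optional observed report-month concentration of
#'   year i-1, ppm (otherwise read from the CO2 record).
#' @return List: `attribution` (an [enso_contribution()] result),
#'   `counterfactual_annual_mean`, `no_nino_month` (ppm, report month),
#'   `trend_month` (ppm or NULL), `model`, `nino`, `emissions`.
#' @export
run_attribution <- function(config, trend_baseline = NULL) {
  stopifnot(inherits(config, "run_config"))
  config <- resolve_inputs(config)
  model <- resolve_model(config, "attribution")
  nino <- resolve_nino(config, "attribution", use_forecast = FALSE)
  eps <- resolve_epsilon(config, "attribution")
  prev <- resolve_prev_mean(config, "attribution")
  cycle <- resolve_cycle(config)
  with_nino <- predict_increment(model, nino$central, eps)$increment
  without <- counterfactual_increment(model, eps)
  att <- enso_contribution(with_nino, without,
                           target_year = config$target_year)
  no_nino_m <- no_nino_monthly(prev, without, cycle, config$report_month)
  trend_m <- NULL
  if (!is.null(config$trend)) {
    if (is.null(trend_baseline)) {
      if (is.null(config$co2))
        stop("attribution: trend extrapolation needs trend_baseline or CO2 record")
      sel <- config$co2$year == config$target_year - config$trend_years &
        config$co2$month == config$report_month
      if (!any(sel)) stop("attribution: baseline month missing from CO2 record")
      trend_baseline <- config$co2$value[sel]
    }
    trend_m <- trend_extrapolation(trend_baseline, config$trend,
                                   config$trend_years)
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_attribution_report(att,
                             path_csv = file.path(config$outdir,
                                                  "attribution.csv"),
                             path_txt = file.path(config$outdir,
                                                  "attribution.txt"),
                             model = model, nino = nino$central,
                             emissions = eps)
    write_provenance(config, config$outdir, "attribution")
  }
  list(attribution = att,
       counterfactual_annual_mean = prev + without,
       no_nino_month = no_nino_m,
       trend_month = trend_m,
       model = model, nino = nino, emissions = eps)
}
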