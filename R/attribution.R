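#' Counterfactual increment with the Nino term zeroed
#'
#' The no-El-Nino annual CO2 increment: the model evaluated with N = 0,
#' leaving only the intercept and the emissions response.
#'
#' @param model a `"co2_increment_model"`.
#' @param emissions previous-year emissions, GtC.
#' @return Counterfactual increment, ppm.
#' @export
counterfactual_increment <- function(model, emissions) {
  predict_increment(model, nino = 0, emissions = emissions)$increment
}

#' ENSO contribution to an annual increment
#'
#' Decomposes an annual CO2 increment into the part attributable to the
#' El Nino (with-minus-without) and the remainder, with the contribution
#' also expressed as a fraction of the with-El-Nino increment.
#'
#' @param with_nino increment with the observed Nino anomaly, ppm.
#' @param without_nino counterfactual (N = 0) increment, ppm.
#' @param target_year optional year label.
#' @return An object of class `"attribution_result"`: `with_nino`,
#'   `without_nino`, `contribution` (ppm), `fraction` (raw ratio),
#'   `fraction_percent` (nearest integer percent; NA with a
#'   `fraction_undefined` flag when `with_nino` is 0).
#' @export
enso_contribution <- function(with_nino, without_nino, target_year = NA) {
  contribution <- with_nino - without_nino
  undefined <- with_nino == 0
  fraction <- if (undefined) NA_real_ else contribution / with_nino
  structure(list(target_year = target_year,
                 with_nino = with_nino,
                 without_nino = without_nino,
                 contribution = contribution,
                 fraction = fraction,
                 fraction_percent = if (undefined) NA_real_
                                    else round(100 * fraction),
                 fraction_undefined = undefined),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("ENSO attribution for %s\n", x$target_year))
  cat(sprintf("  increment with El Nino:    %.2f ppm\n", x$with_nino))
  cat(sprintf("  increment without El Nino: %.2f ppm\n", x$without_nino))
  cat(sprintf("  El Nino contribution:      %.2f ppm", x$contribution))
  if (!x$fraction_undefined)
    cat(sprintf(" (~%d%% of the rise)", x$fraction_percent))
  cat("\n")
  invisible(x)
}

#' No-El-Nino monthly concentration estimate
#'
#' Adds the counterfactual increment to the previous year's annual mean and
#' applies the month's seasonal adjustment factor.  Note the baseline (the
#' previous annual mean) is taken as unaffected by the El Nino; that
#' simplification is inherent to the method.
#'
#' @param prev_annual_mean previous year's observed annual mean, ppm.
#' @param counterfactual_increment no-El-Nino increment, ppm.
#' @param cycle a [seasonal_cycle()].
#' @param month calendar month 1-12.
#' @return Estimated monthly mean concentration, ppm.
#' @export
no_nino_monthly <- function(prev_annual_mean, counterfactual_increment,
                            cycle, month) {
  month <- as.integer(month)
  if (month < 1L || month > 12L) stop("month must be in 1..12")
  prev_annual_mean + counterfactual_increment + cycle$factors[month]
}

#' Trend extrapolation of a monthly concentration
#'
#' Simple linear extrapolation of a recent mean growth trend, the
#' alternative no-El-Nino estimate: last year's monthly value plus trend
#' times horizon.
#'
#' @param monthly_value baseline monthly mean, ppm.
#' @param trend recent trend, ppm per year.
#' @param n_years extrapolation horizon in years (>= 0).
#' @return Extrapolated concentration, ppm.
#' @export
trend_extrapolation <- function(monthly_value, trend, n_years) {
  if (n_years < 0) stop("n_years must be >= 0")
  monthly_value + trend * n_years
}

#' Write an attribution report
#'
#' Tidy CSV plus a human-readable text block laying out coefficients,
#' inputs and the with/without-El-Nino decomposition.
#'
#' @param result an [enso_contribution()] result.
#' @param path_csv,path_txt output files (NULL to skip either).
#' @param model,nino,emissions optional inputs echoed in the text block.
#' @return The report data frame, invisibly.
#' @export
write_attribution_report <- function(result, path_csv = NULL, path_txt = NULL,
                                     model = NULL, nino = NULL,
                                     emissions = NULL) {
  d <- data.frame(target_year = result$target_year,
                  with_nino_ppm = round(result$with_nino, 2),
                  without_nino_ppm = round(result$without_nino, 2),
                  contribution_ppm = round(result$contribution, 2),
                  fraction_percent = result$fraction_percent)
  if (!is.null(path_csv))
    utils::write.csv(d, path_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w")
    on.exit(close(con))
    w <- function(...) cat(sprintf(...), file = con)
    w("El Nino contribution to the annual CO2 increment, %s\n",
      result$target_year)
    w("%-28s %12s %12s\n", "", "with El Nino", "no El Nino")
    if (!is.null(model)) {
      w("%-28s %12.3f %12.3f\n", "alpha1 (ppm/yr)", model$alpha[1], model$alpha[1])
      w("%-28s %12.3f %12.3f\n", "alpha2 (ppm/yr/degC)", model$alpha[2], model$alpha[2])
      w("%-28s %12.3f %12.3f\n", "alpha3 (ppm/GtC)", model$alpha[3], model$alpha[3])
    }
    if (!is.null(nino)) w("%-28s %12.2f %12.2f\n", "N (degC)", nino, 0)
    if (!is.null(emissions))
      w("%-28s %12.2f %12.2f\n", "eps (GtC)", emissions, emissions)
    w("%-28s %12.2f %12.2f\n", "dCO2 (ppm)",
      result$with_nino, result$without_nino)
    w("El Nino contribution: %.2f ppm (~%s%%)\n", result$contribution,
      ifelse(result$fraction_undefined, "NA", result$fraction_percent))
  }
  invisible(d)
}
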