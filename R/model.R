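#' Assemble design rows for the increment regression
#'
#' One row per target year i holding the observed annual CO2 increment
#' dCO2(i), the April(i-1)-March(i) Nino anomaly N(i) and the previous
#' year's emissions eps(i-1).  Emissions are published per calendar year,
#' so the regressor for year i is the year i-1 total; the SST window also
#' straddles the year boundary.  Rows with any missing component are
#' dropped with a message.
#'
#' @param co2 a ppm [monthly_series()].
#' @param nino either a degC [monthly_series()] (window means are computed
#'   per year) or a named numeric vector of per-year window centrals, names
#'   being target years.
#' @param emissions an [emissions_series()].
#' @param years integer vector of target years i to attempt.
#' @param gap_policy passed to [annual_increment()].
#' @return Data frame with columns `year`, `dco2` (ppm), `nino` (degC),
#'   `emissions` (GtC, year i-1).
#' @export
build_design_rows <- function(co2, nino, emissions, years,
                              gap_policy = "strict") {
  years <- as.integer(years)
  nino_for <- if (inherits(nino, "monthly_series")) {
    function(y) tryCatch(window_mean(nino, y), error = function(e) NA_real_)
  } else {
    nv <- nino
    function(y) {
      i <- match(as.character(y), names(nv))
      if (is.na(i)) NA_real_ else as.numeric(nv[i])
    }
  }
  rows <- data.frame(
    year = years,
    dco2 = vapply(years, function(y)
      tryCatch(annual_increment(co2, y, gap_policy),
               error = function(e) NA_real_), numeric(1)),
    nino = vapply(years, nino_for, numeric(1)),
    emissions = vapply(years, function(y)
      emissions_for(emissions, y - 1L), numeric(1)))
  drop <- !stats::complete.cases(rows)
  if (any(drop))
    message(sprintf("dropping %d year(s) with missing components: %s",
                    sum(drop), paste(rows$year[drop], collapse = ", ")))
  rows <- rows[!drop, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no complete design rows")
  rownames(rows) <- NULL
  rows
}

#' Fit the annual CO2 increment regression
#'
#' Calibrates the linear response of the annual CO2 increment to the
#' windowed Nino SST anomaly and to anthropogenic emissions,
#' \deqn{\Delta CO_2(i) = \alpha_1 + \alpha_2 N(i) + \alpha_3 \varepsilon(i-1) + e_i,}
#' by ordinary least squares (QR decomposition via [stats::lm()]).  The
#' intercept alpha1 is in ppm/yr, alpha2 in ppm/yr/degC, alpha3 in ppm/GtC.
#' The residual spread (sample standard deviation of the OLS residuals)
#' drives the default forecast uncertainty.
#'
#' @param rows design rows from [build_design_rows()] (columns `dco2`,
#'   `nino`, `emissions`, optionally `year`).
#' @return An object of class `"co2_increment_model"` with components
#'   `alpha` (named length-3 vector), `residual_sd`, `calibration_years`,
#'   `n_rows`, `rows` and the underlying `fit`.
#' @seealso [increment_model()] to inject published coefficients verbatim;
#'   [predict_increment()]; [forecast_concentrations()].
#' @examples
#' rows <- data.frame(year = 2001:2010, nino = sin(1:10),
#'                    emissions = seq(8, 10, length.out = 10))
#' rows$dco2 <- -0.1 + 0.4 * rows$nino + 0.24 * rows$emissions
#' coef(fit_increment_model(rows))
#' @export
fit_increment_model <- function(rows) {
  need <- c("dco2", "nino", "emissions")
  if (!all(need %in% names(rows)))
    stop("rows need columns: ", paste(need, collapse = ", "))
  if (nrow(rows) < 4L)
    stop("need at least 4 rows to calibrate 3 coefficients")
  fit <- stats::lm(dco2 ~ nino + emissions, data = rows)
  if (fit$rank < 3L)
    stop("rank-deficient design: nino and emissions are collinear")
  alpha <- stats::setNames(as.numeric(stats::coef(fit)),
                           c("alpha1", "alpha2", "alpha3"))
  res <- stats::residuals(fit)
  yrs <- if ("year" %in% names(rows)) range(rows$year) else NULL
  structure(list(alpha = alpha,
                 residual_sd = stats::sd(res),
                 calibration_years = yrs,
                 n_rows = nrow(rows),
                 rows = rows,
                 fit = fit),
            class = "co2_increment_model")
}

#' Increment model from given coefficients
#'
#' Builds the same model object as [fit_increment_model()] but from
#' coefficients supplied verbatim (e.g. published regression tables),
#' bypassing calibration.  Used to reproduce worked forecasts exactly.
#'
#' @param alpha1 intercept, ppm/yr.
#' @param alpha2 Nino response, ppm/yr/degC.
#' @param alpha3 emissions response, ppm/GtC.
#' @param residual_sd residual spread in ppm (NA when unknown).
#' @param calibration_years optional length-2 year range the coefficients
#'   came from.
#' @return A `"co2_increment_model"` (with `fit = NULL`).
#' @export
increment_model <- function(alpha1, alpha2, alpha3, residual_sd = NA_real_,
                            calibration_years = NULL) {
  structure(list(alpha = c(alpha1 = as.numeric(alpha1),
                           alpha2 = as.numeric(alpha2),
                           alpha3 = as.numeric(alpha3)),
                 residual_sd = as.numeric(residual_sd),
                 calibration_years = calibration_years,
                 n_rows = NA_integer_,
                 rows = NULL,
                 fit = NULL),
            class = "co2_increment_model")
}

#' @export
coef.co2_increment_model <- function(object, ...) object$alpha

#' @export
residuals.co2_increment_model <- function(object, ...) {
  if (is.null(object$fit)) stop("model was injected, not calibrated")
  stats::residuals(object$fit)
}

#' @export
fitted.co2_increment_model <- function(object, ...) {
  if (is.null(object$fit)) stop("model was injected, not calibrated")
  stats::fitted(object$fit)
}

#' @export
print.co2_increment_model <- function(x, digits = 3, ...) {
  cat("Annual CO2 increment model: dCO2 = a1 + a2*N + a3*eps\n")
  cat(sprintf("  alpha1 = %+.*f ppm/yr\n", digits, x$alpha[1]))
  cat(sprintf("  alpha2 = %+.*f ppm/yr/degC\n", digits, x$alpha[2]))
  cat(sprintf("  alpha3 = %+.*f ppm/GtC\n", digits, x$alpha[3]))
  if (is.finite(x$residual_sd))
    cat(sprintf("  residual sd = %.*f ppm\n", digits, x$residual_sd))
  if (!is.null(x$fit))
    cat(sprintf("  calibrated on %d years (%d-%d)\n", x$n_rows,
                x$calibration_years[1], x$calibration_years[2]))
  else
    cat("  coefficients supplied verbatim (not calibrated here)\n")
  invisible(x)
}

#' @export
summary.co2_increment_model <- function(object, ...) {
  out <- list(model = object,
              lm_summary = if (!is.null(object$fit)) summary(object$fit))
  class(out) <- "summary.co2_increment_model"
  out
}

#' @export
print.summary.co2_increment_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$lm_summary)) {
    cat("\nOLS detail:\n")
    stats::printCoefmat(x$lm_summary$coefficients)
  }
  invisible(x)
}

#' @export
predict.co2_increment_model <- function(object, newdata, ...) {
  a <- object$alpha
  unname(a[1] + a[2] * newdata$nino + a[3] * newdata$emissions)
}

#' @export
simulate.co2_increment_model <- function(object, nsim = 1, seed = NULL,
                                         newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$rows
  if (is.null(newdata)) stop("newdata required for an injected model")
  mu <- predict(object, newdata)
  sdv <- object$residual_sd
  if (!is.finite(sdv)) stop("residual_sd unknown; cannot simulate")
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sdv)))
}

#' Central increment prediction with uncertainty
#'
#' Evaluates the increment model at one (N, eps) pair and attaches a 2-s.d.
#' uncertainty.  Default policy: `two_sd = 2 * residual_sd` of the
#' calibration; a fixed value may be supplied instead to reproduce printed
#' intervals exactly.
#'
#' @param model a `"co2_increment_model"`.
#' @param nino windowed Nino anomaly N, degC.
#' @param emissions previous-year emissions eps, GtC.
#' @param two_sd optional fixed 2-s.d. half-width in ppm, overriding the
#'   residual-based default.
#' @return List with `increment` (ppm), `two_sd` (ppm) and `components`
#'   (intercept, Nino term alpha2*N, emissions term alpha3*eps).
#' @export
predict_increment <- function(model, nino, emissions, two_sd = NULL) {
  stopifnot(is.finite(nino), is.finite(emissions))
  a <- model$alpha
  comp <- c(intercept = unname(a[1]),
            nino = unname(a[2] * nino),
            emissions = unname(a[3] * emissions))
  if (is.null(two_sd))
    two_sd <- if (is.finite(model$residual_sd)) 2 * model$residual_sd
              else NA_real_
  list(increment = sum(comp), two_sd = two_sd, components = comp)
}

#' Reconstruct historical increments from the model
#'
#' Fitted increments for every design row, for diagnostics and plotting of
#' the reconstruction against observations.
#'
#' @param model a `"co2_increment_model"`.
#' @param rows design rows (default: the calibration rows).
#' @return Data frame with `year` (if present), `observed` and
#'   `reconstructed` increments (ppm).
#' @export
reconstruct_history <- function(model, rows = model$rows) {
  if (is.null(rows)) stop("no rows available")
  out <- data.frame(observed = rows$dco2,
                    reconstructed = predict(model, rows))
  if ("year" %in% names(rows)) out <- cbind(year = rows$year, out)
  out
}

#' @export
plot.co2_increment_model <- function(x, rows = x$rows, ...) {
  h <- reconstruct_history(x, rows)
  xs <- if ("year" %in% names(h)) h$year else seq_len(nrow(h))
  graphics::plot(xs, h$observed, type = "b", pch = 16,
                 xlab = "year", ylab = "annual CO2 increment (ppm)", ...)
  graphics::lines(xs, h$reconstructed, col = "steelblue", lwd = 2)
  graphics::legend("topleft", legend = c("observed", "reconstructed"),
                   col = c("black", "steelblue"), lty = 1, bty = "n")
  invisible(h)
}

#' Downscale an increment forecast to annual and monthly concentrations
#'
#' Adds the forecast increment to the previous year's observed annual mean,
#' then applies the monthly adjustment factors to obtain monthly means.  The
#' monthly means average back to the annual mean because the factors sum to
#' zero.
#'
#' @param prev_annual_mean previous year's observed annual mean, ppm.
#' @param increment forecast increment, ppm (scalar, or the list returned by
#'   [predict_increment()]).
#' @param cycle a [seasonal_cycle()].
#' @param two_sd 2-s.d. half-width applied to the increment, annual and
#'   monthly means alike (taken from `increment` when that is a
#'   [predict_increment()] result).
#' @param target_year forecast year label.
#' @return An object of class `"co2_forecast"`: `target_year`,
#'   `increment_central`, `increment_two_sd`, `annual_mean`,
#'   `monthly_means` (12 values, named by month), `components`.
#' @export
forecast_concentrations <- function(prev_annual_mean, increment, cycle,
                                    two_sd = NA_real_, target_year = NA) {
  components <- NULL
  if (is.list(increment)) {
    if (is.na(two_sd) && !is.null(increment$two_sd)) two_sd <- increment$two_sd
    components <- increment$components
    increment <- increment$increment
  }
  if (!inherits(cycle, "seasonal_cycle")) stop("cycle must be a seasonal_cycle")
  annual <- prev_annual_mean + increment
  structure(list(target_year = target_year,
                 increment_central = increment,
                 increment_two_sd = two_sd,
                 annual_mean = annual,
                 monthly_means = stats::setNames(annual + cycle$factors,
                                                 month.abb),
                 components = components),
            class = "co2_forecast")
}

#' @export
print.co2_forecast <- function(x, ...) {
  pm <- function(v) if (is.finite(x$increment_two_sd))
    sprintf("%.2f +/- %.2f", v, x$increment_two_sd) else sprintf("%.2f", v)
  cat(sprintf("CO2 forecast for %s\n", x$target_year))
  cat(sprintf("  annual increment: %s ppm\n", pm(x$increment_central)))
  cat(sprintf("  annual mean:      %s ppm\n", pm(x$annual_mean)))
  cat(sprintf("  monthly range:    %.2f (%s) to %.2f (%s) ppm\n",
              min(x$monthly_means), month.abb[which.min(x$monthly_means)],
              max(x$monthly_means), month.abb[which.max(x$monthly_means)]))
  invisible(x)
}

#' Serialize an increment model to a plain-text file
#'
#' Key/value (DCF) format holding the coefficients, residual spread,
#' calibration window and an optional provenance hash of the inputs.
#'
#' @param model a `"co2_increment_model"`.
#' @param path output file.
#' @param provenance optional character string (e.g. an input digest).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, provenance = NULL) {
  d <- data.frame(alpha1 = format(model$alpha[1], digits = 17),
                  alpha2 = format(model$alpha[2], digits = 17),
                  alpha3 = format(model$alpha[3], digits = 17),
                  residual_sd = format(model$residual_sd, digits = 17),
                  n_rows = model$n_rows)
  if (!is.null(model$calibration_years)) {
    d$year_from <- model$calibration_years[1]
    d$year_to <- model$calibration_years[2]
  }
  if (!is.null(provenance)) d$provenance <- provenance
  write.dcf(d, path)
  invisible(path)
}

#' Read a serialized increment model
#'
#' @param path file written by [write_model()].
#' @return A `"co2_increment_model"` (injected form).
#' @export
read_model <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  yrs <- if (all(c("year_from", "year_to") %in% names(d)))
    c(as.integer(d$year_from), as.integer(d$year_to)) else NULL
  m <- increment_model(as.numeric(d$alpha1), as.numeric(d$alpha2),
                       as.numeric(d$alpha3), as.numeric(d$residual_sd),
                       calibration_years = yrs)
  m$n_rows <- if ("n_rows" %in% names(d)) as.integer(d$n_rows) else NA_integer_
  m
}
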