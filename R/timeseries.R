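#' Monthly time series of a scalar geophysical quantity
#'
#' Constructs a gap-aware monthly series, the basic container for monthly
#' mean CO2 concentrations (ppm) or SST anomalies (degrees C).  Missing
#' months are simply absent: no NA values are ever stored.
#'
#' @param year integer vector of calendar years.
#' @param month integer vector of months (1-12), same length as `year`.
#' @param value numeric vector of monthly values; non-finite entries are an
#'   error (drop sentinel-coded missing values before construction, or use
#'   [read_monthly_csv()] which does so).
#' @param units one of `"ppm"` or `"degC"`.
#' @return An object of class `"monthly_series"`: a data frame with columns
#'   `year`, `month`, `value`, sorted in calendar order, plus a `units`
#'   attribute.
#' @examples
#' s <- monthly_series(rep(2015, 12), 1:12, 400 + sin(2 * pi * (1:12) / 12))
#' annual_mean(s, 2015)
#' @export
monthly_series <- function(year, month, value, units = c("ppm", "degC")) {
  units <- match.arg(units)
  if (length(year) != length(month) || length(month) != length(value))
    stop("year, month and value must have equal length")
  year <- as.integer(year)
  month <- as.integer(month)
  value <- as.numeric(value)
  if (any(month < 1L | month > 12L))
    stop("month must be in 1..12")
  if (any(!is.finite(value)))
    stop("values must be finite; drop missing months instead of coding them")
  key <- year * 12L + (month - 1L)
  if (anyDuplicated(key))
    stop("duplicate (year, month) pairs")
  o <- order(key)
  out <- data.frame(year = year[o], month = month[o], value = value[o])
  attr(out, "units") <- units
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("Monthly series: %d months, %s, %d-%02d to %d-%02d\n",
              nrow(x), attr(x, "units"),
              x$year[1], x$month[1], x$year[nrow(x)], x$month[nrow(x)]))
  invisible(x)
}

# Values for the 12 months of `year`, NA where absent.
month_values <- function(series, year) {
  v <- rep(NA_real_, 12L)
  sel <- series$year == year
  v[series$month[sel]] <- series$value[sel]
  v
}

#' Annual mean of a monthly series
#'
#' Equal-weight mean of the 12 monthly values of a calendar year, the
#' convention used for annual mean CO2 concentration at Mauna Loa.
#'
#' @param series a [monthly_series()].
#' @param year calendar year.
#' @param gap_policy `"strict"` (default) errors if any month is missing;
#'   `"interpolate"` fills a single missing interior month linearly from its
#'   calendar neighbours within the year (two or more missing months always
#'   error).  Strict is the default for reproducibility.
#' @return The annual mean, in the series units.
#' @export
annual_mean <- function(series, year, gap_policy = c("strict", "interpolate")) {
  gap_policy <- match.arg(gap_policy)
  v <- month_values(series, year)
  miss <- which(is.na(v))
  if (length(miss) > 0L) {
    if (gap_policy == "interpolate" && length(miss) == 1L &&
        miss > 1L && miss < 12L) {
      v[miss] <- (v[miss - 1L] + v[miss + 1L]) / 2
    } else {
      stop(sprintf("year %d is missing month(s) %s", year,
                   paste(miss, collapse = ", ")))
    }
  }
  mean(v)
}

#' Annual increment in a monthly series
#'
#' Difference between the annual means of two successive calendar years,
#' indexed by the later year.  This is the quantity the increment regression
#' forecasts, distinct from the in-year growth rate ([in_year_growth()]).
#'
#' @inheritParams annual_mean
#' @param year the later calendar year; the increment is
#'   `annual_mean(year) - annual_mean(year - 1)`.
#' @return The increment (ppm for a CO2 series).
#' @export
annual_increment <- function(series, year,
                             gap_policy = c("strict", "interpolate")) {
  gap_policy <- match.arg(gap_policy)
  annual_mean(series, year, gap_policy) -
    annual_mean(series, year - 1L, gap_policy)
}

#' In-year growth rate
#'
#' Concentration change across a calendar year, the convention used by the
#' Global Carbon Budget (as opposed to the annual increment).  Implemented
#' as the December monthly mean of `year` minus the December monthly mean of
#' `year - 1`; the single-month convention is isolated here so alternatives
#' can be configured.
#'
#' @inheritParams annual_mean
#' @param boundary_month the month whose year-on-year difference defines the
#'   growth rate (default 12, December).
#' @return The in-year growth (series units per year).
#' @export
in_year_growth <- function(series, year, boundary_month = 12L) {
  boundary_month <- as.integer(boundary_month)
  if (boundary_month < 1L || boundary_month > 12L)
    stop("boundary_month must be in 1..12")
  get1 <- function(y) {
    sel <- series$year == y & series$month == boundary_month
    if (!any(sel))
      stop(sprintf("missing boundary month %d-%02d", y, boundary_month))
    series$value[sel]
  }
  get1(year) - get1(year - 1L)
}

#' Seasonal adjustment factors (mean annual cycle)
#'
#' For each calendar month, the mean offset of that month's value from its
#' year's annual mean, averaged over the reference years.  Used to downscale
#' an annual mean forecast to monthly concentrations.  By construction each
#' year's twelve offsets sum to zero, so the factors do too.
#'
#' @param series a [monthly_series()].
#' @param reference_years integer vector of complete calendar years.
#' @return An object of class `"seasonal_cycle"`: list with `factors` (12
#'   values, series units) and `reference_years`.
#' @export
seasonal_factors <- function(series, reference_years) {
  reference_years <- as.integer(reference_years)
  if (length(reference_years) == 0L)
    stop("reference_years is empty")
  offs <- vapply(reference_years, function(y) {
    month_values(series, y) - annual_mean(series, y)
  }, numeric(12L))
  seasonal_cycle(rowMeans(offs), reference_years)
}

#' Seasonal-cycle object
#'
#' Container for the 12 monthly adjustment factors.  Factors may also be
#' injected directly (e.g. a published table of adjustment factors) instead
#' of computed with [seasonal_factors()].
#'
#' @param factors numeric vector of 12 monthly offsets, summing to zero
#'   within numerical tolerance.
#' @param reference_years the years the factors were derived from, or NULL
#'   for injected factors.
#' @return An object of class `"seasonal_cycle"`.
#' @export
seasonal_cycle <- function(factors, reference_years = NULL) {
  factors <- as.numeric(factors)
  if (length(factors) != 12L)
    stop("need exactly 12 factors")
  if (abs(sum(factors)) > 1e-6 * max(1, max(abs(factors))))
    stop("seasonal factors must sum to zero")
  structure(list(factors = factors, reference_years = reference_years),
            class = "seasonal_cycle")
}

#' @export
print.seasonal_cycle <- function(x, ...) {
  cat("Seasonal adjustment factors (units of the source series):\n")
  print(round(stats::setNames(x$factors, month.abb), 2))
  invisible(x)
}

#' Trend in seasonal-cycle amplitude
#'
#' Per-year amplitude (max minus min of the within-year monthly offsets from
#' the annual mean) and the slope of a straight-line fit of amplitude against
#' year.  A slope indistinguishable from zero supports the stationarity
#' assumption behind seasonal downscaling.
#'
#' @param series a [monthly_series()] with at least 3 complete years.
#' @return List with `amplitude` (data frame of year, amplitude), `slope`
#'   (units per year), `slope_se` (standard error; NA when only the exact
#'   2-point fit is possible) and the underlying `fit`.
#' @export
seasonal_amplitude_trend <- function(series) {
  years <- sort(unique(series$year))
  complete <- years[vapply(years, function(y)
    !anyNA(month_values(series, y)), logical(1))]
  if (length(complete) < 3L)
    stop("need at least 3 complete years")
  amp <- vapply(complete, function(y) {
    off <- month_values(series, y) - annual_mean(series, y)
    max(off) - min(off)
  }, numeric(1))
  d <- data.frame(year = complete, amplitude = amp)
  fit <- stats::lm(amplitude ~ year, data = d)
  # a constructed constant-amplitude series fits exactly; the perfect-fit
  # warning from summary.lm is expected there, not informative
  sm <- suppressWarnings(summary(fit))$coefficients
  list(amplitude = d,
       slope = unname(stats::coef(fit)[2]),
       slope_se = if (nrow(sm) >= 2) sm[2, 2] else NA_real_,
       fit = fit)
}

#' Read a Scripps-style monthly CSV
#'
#' Expects columns year, month, value (header optional when exactly three
#' columns).  Lines beginning with `"` or `%` are comments.  Values equal to
#' the missing sentinel are dropped, never stored.
#'
#' @param path file path.
#' @param units passed to [monthly_series()].
#' @param sentinel missing-value code (default -99.99).
#' @return A [monthly_series()].
#' @export
read_monthly_csv <- function(path, units = c("ppm", "degC"),
                             sentinel = -99.99) {
  units <- match.arg(units)
  lines <- readLines(path)
  lines <- lines[!grepl('^\\s*["%]', lines) & nzchar(trimws(lines))]
  header <- grepl("year", lines[1], ignore.case = TRUE)
  d <- utils::read.csv(text = paste(lines, collapse = "\n"),
                       header = header,
                       col.names = c("year", "month", "value"))
  keep <- abs(d$value - sentinel) > 1e-9
  monthly_series(d$year[keep], d$month[keep], d$value[keep], units)
}

#' Write annual statistics of a CO2 series to tidy CSV
#'
#' One row per year with the annual mean and, where defined, the annual
#' increment and in-year growth rate.  Values are rounded to 2 decimal
#' places at this reporting layer only.
#'
#' @param series a [monthly_series()].
#' @param path output file.
#' @param gap_policy passed to [annual_mean()].
#' @return The data frame written, invisibly.
#' @export
write_annual_stats <- function(series, path, gap_policy = "strict") {
  years <- sort(unique(series$year))
  am <- vapply(years, function(y)
    tryCatch(annual_mean(series, y, gap_policy), error = function(e) NA_real_),
    numeric(1))
  inc <- c(NA, diff(am))
  gr <- vapply(years, function(y)
    tryCatch(in_year_growth(series, y), error = function(e) NA_real_),
    numeric(1))
  d <- data.frame(year = years,
                  annual_mean = round(am, 2),
                  annual_increment = round(inc, 2),
                  in_year_growth = round(gr, 2))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(d)
}
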