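#' Annual anthropogenic emissions series
#'
#' Total anthropogenic carbon emissions (fossil fuel plus land-use change)
#' per calendar year, in GtC.
#'
#' @param year integer vector of calendar years (unique).
#' @param gtc numeric vector of non-negative annual totals, GtC.
#' @return An object of class `"emissions_series"`: a data frame with
#'   columns `year` and `gtc`, sorted by year.
#' @export
emissions_series <- function(year, gtc) {
  if (length(year) != length(gtc)) stop("year and gtc lengths differ")
  year <- as.integer(year)
  gtc <- as.numeric(gtc)
  if (anyDuplicated(year)) stop("duplicate years")
  if (any(!is.finite(gtc)) || any(gtc < 0)) stop("emissions must be >= 0")
  o <- order(year)
  out <- data.frame(year = year[o], gtc = gtc[o])
  class(out) <- c("emissions_series", "data.frame")
  out
}

#' @export
print.emissions_series <- function(x, ...) {
  cat(sprintf("Annual emissions: %d years (%d-%d), %.1f-%.1f GtC\n",
              nrow(x), min(x$year), max(x$year), min(x$gtc), max(x$gtc)))
  invisible(x)
}

#' Look up annual emissions
#'
#' @param emissions an [emissions_series()].
#' @param year calendar year.
#' @return Emissions in GtC, or NA if the year is absent.
#' @export
emissions_for <- function(emissions, year) {
  i <- match(as.integer(year), emissions$year)
  if (is.na(i)) NA_real_ else emissions$gtc[i]
}

#' Read an annual emissions CSV
#'
#' Columns year, gtc (a header is required).  Extra columns (e.g. separate
#' fossil and land-use totals) are ignored; only the total is consumed.
#'
#' @param path file path.
#' @return An [emissions_series()].
#' @export
read_emissions_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("year", "gtc") %in% names(d)))
    stop("emissions CSV needs columns year, gtc")
  emissions_series(d$year, d$gtc)
}
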