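#' Ensemble of monthly SST anomaly series
#'
#' A set of monthly series realizations indexed by member id, representing
#' either observational uncertainty (e.g. a homogenized-observation ensemble)
#' or seasonal-forecast initial-condition spread.
#'
#' @param members named list of [monthly_series()] objects in degC anomaly
#'   units relative to a common climatological baseline (1961-1990 for the
#'   datasets this package emulates).
#' @param source `"observed"` or `"forecast"`.
#' @return An object of class `"ensemble_series"`.
#' @export
ensemble_series <- function(members, source = c("observed", "forecast")) {
  source <- match.arg(source)
  if (length(members) == 0L) stop("ensemble has no members")
  if (is.null(names(members)) || anyDuplicated(names(members)))
    names(members) <- paste0("m", seq_along(members))
  ok <- vapply(members, function(m)
    inherits(m, "monthly_series") && attr(m, "units") == "degC", logical(1))
  if (!all(ok)) stop("all members must be degC monthly_series")
  structure(list(members = members, source = source),
            class = "ensemble_series")
}

#' @export
print.ensemble_series <- function(x, ...) {
  cat(sprintf("SST anomaly ensemble (%s): %d member(s)\n",
              x$source, length(x$members)))
  invisible(x)
}

# Months of the April(i-1)..March(i) window as (year, month) pairs.
window_months <- function(target_year) {
  data.frame(year = c(rep(target_year - 1L, 9L), rep(target_year, 3L)),
             month = c(4:12, 1:3))
}

#' April-March window mean of an SST anomaly series
#'
#' Equal-weight mean of the 12 monthly anomalies from April of `target_year
#' - 1` to March of `target_year`.  This window correlates most strongly
#' with the CO2 increment between the two calendar years it spans.
#'
#' @param member a degC [monthly_series()].
#' @param target_year calendar year i; the window runs Apr(i-1)..Mar(i).
#' @return Window mean anomaly in degC.
#' @export
window_mean <- function(member, target_year) {
  wm <- window_months(as.integer(target_year))
  key <- member$year * 12L + member$month
  idx <- match(wm$year * 12L + wm$month, key)
  if (anyNA(idx)) {
    miss <- wm[is.na(idx), ]
    stop(sprintf("window for %d missing months: %s", target_year,
                 paste(sprintf("%d-%02d", miss$year, miss$month),
                       collapse = ", ")))
  }
  mean(member$value[idx])
}

#' Summarize ensemble realizations
#'
#' @param realizations numeric vector of per-member window means.
#' @return List with `central` (mean) and `two_sd` (twice the sample
#'   standard deviation; 0 for a single realization).
#' @export
ensemble_summary <- function(realizations) {
  if (length(realizations) == 0L) stop("no realizations")
  list(central = mean(realizations),
       two_sd = if (length(realizations) == 1L) 0
                else 2 * stats::sd(realizations))
}

#' Windowed Nino index with ensemble uncertainty
#'
#' @param target_year calendar year i of the Apr(i-1)..Mar(i) window.
#' @param realizations per-realization window means (degC).
#' @return An object of class `"windowed_nino"` with `central`, `two_sd`
#'   and the `realizations`.
#' @export
windowed_nino <- function(target_year, realizations) {
  s <- ensemble_summary(realizations)
  structure(list(target_year = as.integer(target_year),
                 central = s$central, two_sd = s$two_sd,
                 realizations = realizations),
            class = "windowed_nino")
}

#' @export
print.windowed_nino <- function(x, ...) {
  cat(sprintf("Apr-Mar Nino anomaly for %d: %.2f +/- %.2f degC (%d realization(s))\n",
              x$target_year, x$central, x$two_sd, length(x$realizations)))
  invisible(x)
}

#' Combine observed and forecast SST ensembles over the April-March window
#'
#' Splices observed anomalies (window months before the split date) with
#' seasonal-forecast anomalies (split date onward) to form realizations of
#' the windowed Nino index before all window months have been observed.
#'
#' Pairing scheme: `"index"` (default) pairs forecast member j with observed
#' member j, recycling the smaller ensemble, so the realization count equals
#' the larger ensemble size; `"cross"` forms the full cross product.
#'
#' @param obs observed [ensemble_series()], covering Apr(i-1) up to the
#'   month before the split.
#' @param fcst forecast [ensemble_series()], covering the split month
#'   through Mar(i).
#' @param split `c(year, month)`: the first month taken from the forecast.
#' @param target_year calendar year i.
#' @param pairing `"index"` or `"cross"`.
#' @return A [windowed_nino()].
#' @export
combine_obs_forecast <- function(obs, fcst, split, target_year,
                                 pairing = c("index", "cross")) {
  pairing <- match.arg(pairing)
  target_year <- as.integer(target_year)
  wm <- window_months(target_year)
  wkey <- wm$year * 12L + wm$month
  skey <- as.integer(split[1]) * 12L + as.integer(split[2])
  pre <- wm[wkey < skey, ]
  post <- wm[wkey >= skey, ]

  part_mean <- function(member, part) {
    if (nrow(part) == 0L) return(0)
    key <- member$year * 12L + member$month
    idx <- match(part$year * 12L + part$month, key)
    if (anyNA(idx)) {
      miss <- part[is.na(idx), ]
      stop(sprintf("coverage gap at splice: missing %s",
                   paste(sprintf("%d-%02d", miss$year, miss$month),
                         collapse = ", ")))
    }
    sum(member$value[idx])
  }
  obs_sums <- vapply(obs$members, part_mean, numeric(1), part = pre)
  fc_sums <- vapply(fcst$members, part_mean, numeric(1), part = post)

  if (pairing == "index") {
    n <- max(length(obs_sums), length(fc_sums))
    real <- (obs_sums[((seq_len(n) - 1L) %% length(obs_sums)) + 1L] +
             fc_sums[((seq_len(n) - 1L) %% length(fc_sums)) + 1L]) / 12
  } else {
    real <- as.vector(outer(obs_sums, fc_sums, "+")) / 12
  }
  windowed_nino(target_year, unname(real))
}

#' Convert an absolute SST series to anomalies
#'
#' Subtracts a per-month climatology (e.g. 1961-1990 monthly means) from an
#' absolute series.  Baseline construction from gridded SST is out of scope;
#' the climatology is supplied by the caller.
#'
#' @param series a degC [monthly_series()] of absolute temperatures.
#' @param climatology numeric vector of 12 monthly baseline values.
#' @return A degC [monthly_series()] of anomalies.
#' @export
to_anomalies <- function(series, climatology) {
  if (length(climatology) != 12L) stop("climatology must have 12 values")
  monthly_series(series$year, series$month,
                 series$value - climatology[series$month], units = "degC")
}

#' Read a long-format ensemble CSV
#'
#' Columns: member, year, month, anomaly_degC and optionally source.
#'
#' @param path file path.
#' @param source ensemble source tag; when the file has a `source` column
#'   the rows are filtered to this tag (so one file can hold both
#'   ensembles).  Taken from the file when omitted and unambiguous.
#' @return An [ensemble_series()].
#' @export
read_ensemble_csv <- function(path, source = NULL) {
  d <- utils::read.csv(path)
  need <- c("member", "year", "month", "anomaly_degC")
  if (!all(need %in% names(d)))
    stop("ensemble CSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(source)) {
    if (!"source" %in% names(d) || length(unique(d$source)) != 1L)
      stop("source tag not determinable from file; pass source=")
    source <- unique(d$source)
  } else if ("source" %in% names(d)) {
    d <- d[d$source == source, , drop = FALSE]
    if (nrow(d) == 0L)
      stop(sprintf("no rows with source '%s' in %s", source, path))
  }
  members <- lapply(split(d, d$member), function(g)
    monthly_series(g$year, g$month, g$anomaly_degC, units = "degC"))
  ensemble_series(members, source = source)
}
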