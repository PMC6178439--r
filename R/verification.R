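#' Verify a forecast interval against an observation
#'
#' A hit is an observation within `two_sd` of the central value, inclusive
#' at the boundary (a tie counts as a hit; ties are adjudicated with a
#' small numerical margin so that values equal to the bound at the printed
#' precision are not lost to floating-point representation).
#'
#' @param central forecast central value.
#' @param two_sd half-width of the forecast range (>= 0).
#' @param observed observed value.
#' @return List with `hit` (logical) and `error` (observed minus central).
#' @export
verify_interval <- function(central, two_sd, observed) {
  if (two_sd < 0) stop("two_sd must be >= 0")
  err <- observed - central
  tol <- 1e-9 * max(1, abs(central), two_sd)
  list(hit = abs(err) <= two_sd + tol, error = err)
}

#' Count monthly forecast hits
#'
#' Number of months (out of 12) whose observed concentration lies within
#' `two_sd` of the forecast, boundary inclusive.
#'
#' @param forecast_months 12 forecast monthly means, ppm.
#' @param two_sd half-width of the monthly forecast range, ppm.
#' @param observed_months 12 observed monthly means, ppm.
#' @return Integer in 0..12.
#' @export
monthly_hit_count <- function(forecast_months, two_sd, observed_months) {
  if (length(forecast_months) != 12L || length(observed_months) != 12L)
    stop("need 12 forecast and 12 observed months")
  sum(vapply(1:12, function(m)
    verify_interval(forecast_months[m], two_sd, observed_months[m])$hit,
    logical(1)))
}

#' Probability of at least one interval miss in k years
#'
#' Under independent, normally distributed forecast errors, a central
#' +/- 2 s.d. interval covers each year with probability equal to the
#' Gaussian mass within two standard deviations (about 95.45%, so a miss
#' rate of about 4.55% per year, computed from the error function rather
#' than hard-coded).  Over k years the probability that at least one
#' observation falls outside the range is `1 - coverage^k`.
#'
#' @param k_years number of forecast years (>= 0).
#' @param coverage per-year interval coverage probability; default the
#'   Gaussian +/- 2 s.d. mass `pnorm(2) - pnorm(-2)`.
#' @return Probability in `[0, 1]`.
#' @export
miss_probability <- function(k_years, coverage = stats::pnorm(2) - stats::pnorm(-2)) {
  if (any(k_years < 0)) stop("k_years must be >= 0")
  if (any(coverage <= 0 | coverage > 1)) stop("coverage must be in (0, 1]")
  1 - coverage^k_years
}

#' Build a verification report
#'
#' Per-quantity interval verification plus the monthly hit count.
#'
#' @param quantities data frame with columns `name`, `central`, `two_sd`,
#'   `observed` (e.g. the increment and the annual mean).
#' @param forecast_months,observed_months optional 12-vectors for the
#'   monthly hit count.
#' @param monthly_two_sd half-width for the monthly check (defaults to the
#'   first quantity's `two_sd`).
#' @return An object of class `"verification_report"`: the per-quantity
#'   table with `hit` and `error` columns, and `monthly_hits` (or NA).
#' @export
verification_report <- function(quantities, forecast_months = NULL,
                                observed_months = NULL,
                                monthly_two_sd = quantities$two_sd[1]) {
  v <- Map(verify_interval, quantities$central, quantities$two_sd,
           quantities$observed)
  quantities$hit <- vapply(v, `[[`, logical(1), "hit")
  quantities$error <- vapply(v, `[[`, numeric(1), "error")
  mh <- if (!is.null(forecast_months) && !is.null(observed_months))
    monthly_hit_count(forecast_months, monthly_two_sd, observed_months)
  else NA_integer_
  structure(list(quantities = quantities, monthly_hits = mh),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  q <- x$quantities
  cat("Forecast verification\n")
  for (i in seq_len(nrow(q)))
    cat(sprintf("  %-24s %8.2f +/- %.2f vs %8.2f  %s (error %+.2f)\n",
                q$name[i], q$central[i], q$two_sd[i], q$observed[i],
                if (q$hit[i]) "HIT " else "MISS", q$error[i]))
  if (!is.na(x$monthly_hits))
    cat(sprintf("  months within range: %d of 12\n", x$monthly_hits))
  invisible(x)
}

#' Write a verification report
#'
#' @param report a [verification_report()].
#' @param path_csv,path_txt output files (NULL to skip either).
#' @return The quantity table, invisibly.
#' @export
write_verification_report <- function(report, path_csv = NULL,
                                      path_txt = NULL) {
  q <- report$quantities
  q$central <- round(q$central, 2)
  q$observed <- round(q$observed, 2)
  q$error <- round(q$error, 2)
  if (!is.null(path_csv))
    utils::write.csv(q, path_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(path_txt)) {
    sink(path_txt)
    on.exit(sink())
    print(report)
  }
  invisible(q)
}
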