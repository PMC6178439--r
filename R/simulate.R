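#' Configuration for the synthetic input generator
#'
#' Defines a complete synthetic study: a monthly Nino anomaly index (AR(1)),
#' an annual emissions trajectory, a monthly CO2 record whose annual
#' increments follow the increment regression exactly (plus Gaussian
#' residual), and SST anomaly ensembles around the Nino truth.  Defaults
#' emulate the 1959-2016 observational record: annual April-March Nino
#' means spanning roughly -1.5 to +2.0 degC, emissions rising from about
#' 2.5 GtC to 11.1 GtC with an 8.4 GtC value at the 1997 analogue, a ~6 ppm
#' peak-to-trough May-maximum/September-minimum seasonal cycle, and
#' ensemble spreads giving a combined windowed-index uncertainty of about
#' +/- 0.2 degC (2 s.d.).
#'
#' @param start_year,end_year simulated year range (>= 10 years).
#' @param alpha true coefficients (alpha1 ppm/yr, alpha2 ppm/yr/degC,
#'   alpha3 ppm/GtC) generating the increments.
#' @param residual_sd Gaussian residual on the annual increment, ppm.
#'   Noise enters at the increment level so the regression holds exactly in
#'   expectation; optional monthly observation noise is separate.
#' @param monthly_noise_sd optional monthly CO2 observation noise, ppm
#'   (default 0, off).
#' @param phi monthly AR(1) coefficient of the Nino index, 0 <= phi < 1.
#' @param innovation_sd AR(1) innovation standard deviation, degC.
#' @param seasonal_factors 12 zero-sum monthly CO2 offsets, ppm.
#' @param co2_start annual mean CO2 of the first year, ppm.
#' @param emissions_start emissions in `start_year`, GtC.
#' @param emissions_growth linear growth, GtC per year.
#' @param emissions_curvature quadratic term, GtC per year squared.
#' @param emissions_spikes named numeric: additional GtC in given years.
#' @param obs_members,fcst_members ensemble sizes.
#' @param member_sd per-month Gaussian member noise, degC.
#' @param split_month first month of the forecast-ensemble coverage in the
#'   April-March window of the final year (default 11: November, giving 7
#'   observed + 5 forecast months).
#' @param seed integer RNG seed; every stochastic generator derives its
#'   stream from it.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(start_year = 1959L, end_year = 2016L,
                             alpha = c(-0.132, 0.415, 0.237),
                             residual_sd = 0.25,
                             monthly_noise_sd = 0,
                             phi = 0.92, innovation_sd = 0.36,
                             seasonal_factors = c(0.00, 0.65, 1.50, 2.40,
                                                  3.00, 2.10, 0.57, -1.50,
                                                  -2.97, -2.85, -2.00, -0.90),
                             co2_start = 316,
                             emissions_start = 2.5,
                             emissions_growth = 0.15883608,
                             emissions_curvature = -9.40245e-5,
                             emissions_spikes = NULL,
                             obs_members = 10L, fcst_members = 42L,
                             member_sd = 0.35,
                             split_month = 11L,
                             seed = 42L) {
  cfg <- list(start_year = as.integer(start_year),
              end_year = as.integer(end_year),
              alpha = as.numeric(alpha),
              residual_sd = residual_sd,
              monthly_noise_sd = monthly_noise_sd,
              phi = phi, innovation_sd = innovation_sd,
              seasonal_factors = as.numeric(seasonal_factors),
              co2_start = co2_start,
              emissions_start = emissions_start,
              emissions_growth = emissions_growth,
              emissions_curvature = emissions_curvature,
              emissions_spikes = emissions_spikes,
              obs_members = as.integer(obs_members),
              fcst_members = as.integer(fcst_members),
              member_sd = member_sd,
              split_month = as.integer(split_month),
              seed = as.integer(seed))
  if (cfg$end_year - cfg$start_year + 1L < 10L)
    stop("year range must cover at least 10 years")
  if (length(cfg$alpha) != 3L) stop("alpha must have 3 components")
  if (cfg$phi < 0 || cfg$phi >= 1) stop("phi must satisfy 0 <= phi < 1")
  if (any(c(cfg$residual_sd, cfg$innovation_sd, cfg$member_sd,
            cfg$monthly_noise_sd) < 0))
    stop("spreads must be >= 0")
  if (length(cfg$seasonal_factors) != 12L ||
      abs(sum(cfg$seasonal_factors)) > 1e-8)
    stop("seasonal_factors must be 12 values summing to 0")
  class(cfg) <- "generator_config"
  cfg
}

#' Simulate a monthly Nino anomaly index
#'
#' Stationary AR(1) process at monthly resolution, initialized from its
#' stationary distribution, covering January of the start year through
#' December of the end year.  Seed-reproducible (Mersenne-Twister via
#' [set.seed()]).
#'
#' @param config a [generator_config()].
#' @return A degC [monthly_series()].
#' @export
simulate_nino <- function(config) {
  set.seed(config$seed + 1L)
  years <- config$start_year:config$end_year
  n <- length(years) * 12L
  x <- numeric(n)
  sd_stat <- if (config$innovation_sd == 0) 0
             else config$innovation_sd / sqrt(1 - config$phi^2)
  x[1] <- stats::rnorm(1, 0, sd_stat)
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, config$innovation_sd)
    for (t in 2:n) x[t] <- config$phi * x[t - 1] + e[t - 1]
  }
  monthly_series(rep(years, each = 12L), rep(1:12, length(years)), x,
                 units = "degC")
}

#' Simulate an annual emissions trajectory
#'
#' Quadratic-in-time trajectory plus optional year spikes (emulating, for
#' example, a land-use emissions spike in a strong fire year).
#'
#' @param config a [generator_config()].
#' @return An [emissions_series()].
#' @export
simulate_emissions <- function(config) {
  years <- config$start_year:config$end_year
  t <- years - config$start_year
  g <- config$emissions_start + config$emissions_growth * t +
    config$emissions_curvature * t^2
  if (!is.null(config$emissions_spikes)) {
    i <- match(as.integer(names(config$emissions_spikes)), years)
    g[i[!is.na(i)]] <- g[i[!is.na(i)]] +
      as.numeric(config$emissions_spikes)[!is.na(i)]
  }
  emissions_series(years, g)
}

#' Simulate a monthly CO2 record with known ground truth
#'
#' Annual increments are generated exactly from the increment regression
#' (true alphas applied to the windowed Nino index and lagged emissions)
#' plus a Gaussian residual; annual means accumulate the increments from
#' `co2_start`, and monthly values add the fixed seasonal factors (plus
#' optional monthly observation noise).
#'
#' @param config a [generator_config()].
#' @param nino degC [monthly_series()] from [simulate_nino()].
#' @param emissions an [emissions_series()] from [simulate_emissions()].
#' @return List: `co2` (ppm [monthly_series()]), `truth` (data frame of
#'   year, increment, nino, emissions, contribution = alpha2 * N, and
#'   annual_mean), and `alpha` (the generating coefficients).
#' @export
simulate_co2 <- function(config, nino, emissions) {
  set.seed(config$seed + 2L)
  years <- config$start_year:config$end_year
  inc_years <- years[-1]
  N <- vapply(inc_years, function(y) window_mean(nino, y), numeric(1))
  eps <- vapply(inc_years, function(y) {
    e <- emissions_for(emissions, y - 1L)
    if (is.na(e)) stop(sprintf("emissions do not cover year %d", y - 1L))
    e
  }, numeric(1))
  a <- config$alpha
  inc <- a[1] + a[2] * N + a[3] * eps +
    stats::rnorm(length(inc_years), 0, config$residual_sd)
  am <- config$co2_start + c(0, cumsum(inc))
  vals <- rep(am, each = 12L) + rep(config$seasonal_factors, length(years))
  if (config$monthly_noise_sd > 0)
    vals <- vals + stats::rnorm(length(vals), 0, config$monthly_noise_sd)
  list(co2 = monthly_series(rep(years, each = 12L),
                            rep(1:12, length(years)), vals, units = "ppm"),
       truth = data.frame(year = inc_years, increment = inc, nino = N,
                          emissions = eps, contribution = a[2] * N,
                          annual_mean = am[-1]),
       alpha = a)
}

#' Simulate observed and forecast SST anomaly ensembles
#'
#' Members are the Nino truth plus independent per-month Gaussian noise.
#' Observed members cover the full index history up to the month before the
#' split; forecast members cover the split month through March of the
#' target year.
#'
#' @param config a [generator_config()].
#' @param nino the truth series from [simulate_nino()].
#' @param target_year year whose April-March window the forecast completes
#'   (default the final simulated year).
#' @return List with `observed` and `forecast` [ensemble_series()] and the
#'   `split` `c(year, month)` used.
#' @export
simulate_sst_ensembles <- function(config, nino,
                                   target_year = config$end_year) {
  set.seed(config$seed + 3L)
  split <- c(target_year - 1L, config$split_month)
  skey <- split[1] * 12L + split[2]
  endkey <- target_year * 12L + 3L
  key <- nino$year * 12L + nino$month
  obs_rows <- key < skey
  fc_rows <- key >= skey & key <= endkey
  make <- function(rows, n) {
    lapply(seq_len(n), function(j)
      monthly_series(nino$year[rows], nino$month[rows],
                     nino$value[rows] +
                       stats::rnorm(sum(rows), 0, config$member_sd),
                     units = "degC"))
  }
  list(observed = ensemble_series(make(obs_rows, config$obs_members),
                                  source = "observed"),
       forecast = ensemble_series(make(fc_rows, config$fcst_members),
                                  source = "forecast"),
       split = split)
}

#' Simulate a complete input bundle
#'
#' Convenience wrapper running all four generators with streams derived
#' from the configured seed.
#'
#' @param config a [generator_config()].
#' @return List: `config`, `nino`, `emissions`, `co2`, `truth`, `alpha`,
#'   `ensembles`.
#' @export
simulate_bundle <- function(config = generator_config()) {
  nino <- simulate_nino(config)
  emissions <- simulate_emissions(config)
  sim <- simulate_co2(config, nino, emissions)
  ens <- simulate_sst_ensembles(config, nino)
  list(config = config, nino = nino, emissions = emissions,
       co2 = sim$co2, truth = sim$truth, alpha = sim$alpha,
       ensembles = ens)
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the three input files in the package's reader formats plus a
#' ground-truth sidecar for tests: `co2_monthly.csv`,
#' `sst_ensembles.csv` (long format, observed and forecast members),
#' `emissions_annual.csv`, `ground_truth.csv` (per-year truth) and
#' `ground_truth_model.txt` (true alphas and residual sd).
#'
#' @param config a [generator_config()].
#' @param directory writable output directory (created if absent).
#' @return Named character vector of the file paths written.
#' @export
write_fixture_bundle <- function(config, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  b <- simulate_bundle(config)
  p <- c(co2 = file.path(directory, "co2_monthly.csv"),
         sst = file.path(directory, "sst_ensembles.csv"),
         emissions = file.path(directory, "emissions_annual.csv"),
         truth = file.path(directory, "ground_truth.csv"),
         model = file.path(directory, "ground_truth_model.txt"))
  utils::write.csv(data.frame(year = b$co2$year, month = b$co2$month,
                              value = b$co2$value),
                   p["co2"], row.names = FALSE, quote = FALSE)
  long <- function(ens, tag) do.call(rbind, lapply(names(ens$members),
    function(id) {
      m <- ens$members[[id]]
      data.frame(member = paste0(tag, "_", id), year = m$year,
                 month = m$month, anomaly_degC = m$value, source = tag)
    }))
  utils::write.csv(rbind(long(b$ensembles$observed, "observed"),
                         long(b$ensembles$forecast, "forecast")),
                   p["sst"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(year = b$emissions$year, gtc = b$emissions$gtc),
                   p["emissions"], row.names = FALSE, quote = FALSE)
  utils::write.csv(b$truth, p["truth"], row.names = FALSE, quote = FALSE)
  write_model(increment_model(b$alpha[1], b$alpha[2], b$alpha[3],
                              config$residual_sd), p["model"])
  p
}

#' Read back a fixture bundle
#'
#' @param directory directory written by [write_fixture_bundle()].
#' @return List with `co2`, `observed`, `forecast`, `emissions`, `truth`
#'   (data frame) and `true_model`.
#' @export
read_fixture_bundle <- function(directory) {
  sst <- utils::read.csv(file.path(directory, "sst_ensembles.csv"))
  part <- function(tag) {
    d <- sst[sst$source == tag, ]
    ensemble_series(lapply(split(d, d$member), function(g)
      monthly_series(g$year, g$month, g$anomaly_degC, units = "degC")),
      source = tag)
  }
  list(co2 = read_monthly_csv(file.path(directory, "co2_monthly.csv")),
       observed = part("observed"),
       forecast = part("forecast"),
       emissions = read_emissions_csv(file.path(directory,
                                                "emissions_annual.csv")),
       truth = utils::read.csv(file.path(directory, "ground_truth.csv")),
       true_model = read_model(file.path(directory,
                                         "ground_truth_model.txt")))
}
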