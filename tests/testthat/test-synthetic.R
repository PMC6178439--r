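test_that("generator config validates its parameters", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(start_year = 2000, end_year = 2005),
               "10 years")
  expect_error(generator_config(phi = 1), "phi")
  expect_error(generator_config(residual_sd = -1), ">= 0")
  expect_error(generator_config(seasonal_factors = rep(1, 12)), "summing to 0")
})

test_that("the Nino simulator is a seed-reproducible AR(1)", {
  cfg <- generator_config(seed = 5)
  expect_equal(simulate_nino(cfg), simulate_nino(cfg))
  expect_false(isTRUE(all.equal(simulate_nino(cfg)$value,
                                simulate_nino(generator_config(seed = 6))$value)))

  # zero innovations -> identically zero series
  still <- simulate_nino(generator_config(phi = 0, innovation_sd = 0))
  expect_equal(still$value, rep(0, length(still$value)))

  # lag-1 autocorrelation close to phi over a long run
  long <- simulate_nino(generator_config(start_year = 1900, end_year = 2016,
                                         seed = 8))
  ac <- acf(long$value, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(ac, 0.92, tolerance = 0.05)
})

test_that("annual windowed means of the default Nino index are El-Nino-like", {
  # spread comparable to the observed record, which spans about -1.5..+2 degC
  cfg <- generator_config(seed = 42)
  nino <- simulate_nino(cfg)
  ann <- vapply(1960:2016, window_mean, numeric(1), member = nino)
  expect_gt(max(ann) - min(ann), 2)
  expect_lt(max(abs(ann)), 3.5)
})

test_that("emissions trajectory matches its anchors", {
  cfg <- generator_config()
  e <- simulate_emissions(cfg)
  expect_equal(emissions_for(e, 1959), 2.5)
  expect_equal(emissions_for(e, 2015) - emissions_for(e, 1997), 2.7,
               tolerance = 0.001)
  expect_true(all(diff(e$gtc) > 0))

  flat <- simulate_emissions(generator_config(emissions_growth = 0,
                                              emissions_curvature = 0))
  expect_equal(flat$gtc, rep(2.5, nrow(flat)))

  spiky <- simulate_emissions(generator_config(
    emissions_spikes = c("1997" = 0.8)))
  expect_equal(emissions_for(spiky, 1997) - emissions_for(e, 1997), 0.8)
})

test_that("the CO2 simulator closes the loop with calibration", {
  cfg <- generator_config(residual_sd = 0, seed = 17)
  b <- simulate_bundle(cfg)
  rows <- build_design_rows(b$co2, setNames(b$truth$nino, b$truth$year),
                            b$emissions, 1960:2016)
  m <- fit_increment_model(rows)
  expect_equal(unname(coef(m)), cfg$alpha, tolerance = 1e-8)
  expect_equal(m$residual_sd, 0, tolerance = 1e-8)

  # zero seasonal amplitude: every month equals its annual mean
  flat <- simulate_bundle(generator_config(seasonal_factors = rep(0, 12),
                                           seed = 17))
  expect_equal(annual_mean(flat$co2, 2000),
               flat$co2$value[flat$co2$year == 2000][1])
})

test_that("ground truth is self-consistent", {
  b <- simulate_bundle(generator_config(seed = 23))
  # increments telescope to the true annual means
  expect_equal(b$config$co2_start + cumsum(b$truth$increment),
               b$truth$annual_mean)
  expect_equal(vapply(b$truth$year, annual_mean, numeric(1), series = b$co2),
               b$truth$annual_mean)
  expect_equal(b$truth$contribution, b$alpha[2] * b$truth$nino)
})

test_that("alpha2 sampling error matches the analytic OLS prediction", {
  cfg <- generator_config(start_year = 1959, end_year = 2015, seed = 31)
  nino <- simulate_nino(cfg)
  emissions <- simulate_emissions(cfg)
  years <- 1960:2015  # 56 calibration rows
  N <- vapply(years, window_mean, numeric(1), member = nino)
  eps <- vapply(years - 1, emissions_for, numeric(1), emissions = emissions)
  X <- cbind(1, N, eps)
  sigma <- cfg$residual_sd
  se_analytic <- sqrt(sigma^2 * solve(crossprod(X))[2, 2])

  set.seed(32)
  est <- replicate(300, {
    d <- data.frame(nino = N, emissions = eps,
                    dco2 = drop(X %*% cfg$alpha) + rnorm(56, 0, sigma))
    coef(fit_increment_model(d))["alpha2"]
  })
  rmse <- sqrt(mean((est - cfg$alpha[2])^2))
  expect_equal(rmse, se_analytic, tolerance = 0.15)
})

test_that("SST ensembles sit around truth with realistic combined spread", {
  cfg <- generator_config(seed = 37)
  nino <- simulate_nino(cfg)

  # zero member noise: every member equals truth over its coverage
  ens0 <- simulate_sst_ensembles(generator_config(member_sd = 0, seed = 37),
                                 nino)
  m1 <- ens0$observed$members[[1]]
  key <- paste(nino$year, nino$month)
  expect_equal(m1$value, nino$value[match(paste(m1$year, m1$month), key)])

  # many members: ensemble centre converges on truth
  big <- simulate_sst_ensembles(generator_config(obs_members = 200,
                                                 fcst_members = 200,
                                                 seed = 39), nino)
  wn_big <- combine_obs_forecast(big$observed, big$forecast, big$split, 2016)
  expect_equal(wn_big$central, window_mean(nino, 2016), tolerance = 0.03)

  # default spreads give a combined window two_sd of about 0.2 degC
  ens <- simulate_sst_ensembles(cfg, nino)
  wn <- combine_obs_forecast(ens$observed, ens$forecast, ens$split, 2016)
  expect_lt(abs(wn$two_sd - 0.2), 0.05)
})

test_that("fixture bundles round-trip through their files", {
  cfg <- generator_config(start_year = 2000, end_year = 2012, seed = 41,
                          obs_members = 3, fcst_members = 4)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(cfg, dir)
  expect_true(all(file.exists(paths)))

  b <- simulate_bundle(cfg)
  back <- read_fixture_bundle(dir)
  expect_equal(back$co2$value, b$co2$value)
  expect_equal(back$emissions$gtc, b$emissions$gtc)
  expect_equal(nrow(back$truth), nrow(b$truth))
  expect_equal(back$truth$increment, b$truth$increment)
  # sidecar alphas equal the config alphas
  expect_equal(unname(coef(back$true_model)), cfg$alpha)
  expect_equal(length(back$observed$members), 3L)
  expect_equal(length(back$forecast$members), 4L)
})

test_that("full pipeline on a default bundle recovers the injected contribution", {
  cfg <- generator_config(seed = 43)
  b <- simulate_bundle(cfg)
  rows <- build_design_rows(b$co2, setNames(b$truth$nino, b$truth$year),
                            b$emissions, 1960:2015)
  m <- fit_increment_model(rows)
  i <- nrow(b$truth)  # the 2016 analogue
  est <- predict_increment(m, b$truth$nino[i], b$truth$emissions[i])$increment -
    counterfactual_increment(m, b$truth$emissions[i])
  se_a2 <- summary(m$fit)$coefficients["nino", 2]
  expect_lt(abs(est - b$truth$contribution[i]),
            2 * se_a2 * abs(b$truth$nino[i]) + 1e-12)
})
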