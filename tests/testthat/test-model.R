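test_that("build_design_rows pairs increments with windowed N and lagged emissions", {
  cfg <- generator_config(start_year = 2000, end_year = 2012, seed = 11)
  b <- simulate_bundle(cfg)
  rows <- build_design_rows(b$co2, setNames(b$truth$nino, b$truth$year),
                            b$emissions, 2001:2012)
  expect_equal(rows$year, b$truth$year)
  expect_equal(rows$dco2, b$truth$increment)
  expect_equal(rows$nino, b$truth$nino)
  expect_equal(rows$emissions, b$truth$emissions)

  # single resolvable year -> exactly one row
  one <- build_design_rows(b$co2, setNames(b$truth$nino, b$truth$year),
                           b$emissions, 2005)
  expect_equal(nrow(one), 1L)

  # years lacking components are dropped with a message, not an error
  expect_message(
    some <- build_design_rows(b$co2, setNames(b$truth$nino, b$truth$year),
                              b$emissions, 1999:2012),
    "dropping")
  expect_equal(nrow(some), 12L)
  expect_error(
    suppressMessages(build_design_rows(b$co2,
                                       setNames(b$truth$nino, b$truth$year),
                                       b$emissions, 1990:1995)),
    "no complete design rows")

  # a degC monthly series is accepted in place of precomputed centrals
  rows2 <- build_design_rows(b$co2, b$nino, b$emissions, 2001:2012)
  expect_equal(rows2$nino, rows$nino)
})

test_that("calibration recovers noiseless coefficients exactly", {
  set.seed(3)
  rows <- data.frame(year = 2001:2012,
                     nino = rnorm(12),
                     emissions = seq(8, 10, length.out = 12))
  rows$dco2 <- -0.132 + 0.415 * rows$nino + 0.237 * rows$emissions
  m <- fit_increment_model(rows)
  expect_equal(unname(coef(m)), c(-0.132, 0.415, 0.237), tolerance = 1e-10)
  expect_equal(m$residual_sd, 0, tolerance = 1e-10)
  expect_equal(m$calibration_years, c(2001, 2012))
  expect_equal(m$n_rows, 12L)
})

test_that("calibration rejects degenerate designs", {
  rows <- data.frame(dco2 = 1:3, nino = 1:3, emissions = 4:6)
  expect_error(fit_increment_model(rows), "at least 4 rows")
  col <- data.frame(dco2 = rnorm(6), nino = 1:6, emissions = 2 * (1:6))
  expect_error(fit_increment_model(col), "collinear")
})

test_that("OLS residual identities hold on calibration data", {
  set.seed(4)
  rows <- data.frame(nino = rnorm(20), emissions = seq(5, 11, length.out = 20))
  rows$dco2 <- 0.1 + 0.4 * rows$nino + 0.2 * rows$emissions + rnorm(20, 0, 0.3)
  m <- fit_increment_model(rows)
  expect_equal(sum(residuals(m)), 0, tolerance = 1e-10)
  h <- reconstruct_history(m, rows)
  expect_equal(mean(h$observed - h$reconstructed), 0, tolerance = 1e-10)
  expect_equal(h$reconstructed, unname(fitted(m)))
})

test_that("reconstruction with the ENSO term beats an emissions-only model", {
  # paired Monte-Carlo comparison on noisy synthetic rows
  set.seed(5)
  wins <- 0L
  for (r in 1:50) {
    n <- 40
    rows <- data.frame(nino = rnorm(n, 0, 0.8),
                       emissions = seq(4, 11, length.out = n))
    rows$dco2 <- -0.1 + 0.4 * rows$nino + 0.23 * rows$emissions +
      rnorm(n, 0, 0.25)
    truth <- -0.1 + 0.4 * rows$nino + 0.23 * rows$emissions
    full <- fitted(lm(dco2 ~ nino + emissions, rows))
    reduced <- fitted(lm(dco2 ~ emissions, rows))
    if (cor(full, truth) > cor(reduced, truth)) wins <- wins + 1L
  }
  expect_gte(wins, 48L)
})

test_that("predict_increment reproduces the worked forecasts", {
  m <- increment_model(alphas_published[1], alphas_published[2],
                       alphas_published[3])
  expect_equal(round(predict_increment(m, 2.02, 10.3)$increment, 2), 3.15)
  expect_equal(round(predict_increment(m, 2.02, 10.84)$increment, 2), 3.28)
  expect_equal(predict_increment(m, 0, 0)$increment, alphas_published[1])

  p <- predict_increment(m, 2.02, 10.3)
  expect_equal(unname(p$components),
               c(-0.132, 0.415 * 2.02, 0.237 * 10.3))
  expect_equal(sum(p$components), p$increment)
})

test_that("prediction is affine; finite differences recover the slopes", {
  m <- increment_model(0.045, 0.426, 0.214, residual_sd = 0.25)
  f <- function(n, e) predict_increment(m, n, e)$increment
  expect_equal(f(1.5, 9) - f(0.5, 9), 0.426)
  expect_equal(f(1, 10) - f(1, 9), 0.214)
  # affine in each argument: midpoint value equals mean of endpoints
  expect_equal(f(1, 9), (f(0, 9) + f(2, 9)) / 2)
  expect_equal(f(1, 9), (f(1, 8) + f(1, 10)) / 2)
})

test_that("uncertainty policy defaults to 2 x residual sd with fixed override", {
  m <- increment_model(0, 0.4, 0.2, residual_sd = 0.25)
  expect_equal(predict_increment(m, 1, 10)$two_sd, 0.5)
  expect_equal(predict_increment(m, 1, 10, two_sd = 0.53)$two_sd, 0.53)
  expect_true(is.na(predict_increment(increment_model(0, 0.4, 0.2),
                                      1, 10)$two_sd))
})

test_that("estimator bias shrinks as the calibration record grows", {
  set.seed(6)
  bias_at <- function(n, reps = 60) {
    est <- replicate(reps, {
      rows <- data.frame(nino = rnorm(n, 0, 0.8),
                         emissions = seq(4, 11, length.out = n))
      rows$dco2 <- -0.132 + 0.415 * rows$nino + 0.237 * rows$emissions +
        rnorm(n, 0, 0.25)
      coef(fit_increment_model(rows))["alpha2"]
    })
    abs(mean(est) - 0.415)
  }
  b <- vapply(c(20, 56, 200), bias_at, numeric(1))
  expect_lt(b[3], 0.02)
  expect_lt(b[3], b[1] + 0.02)  # monotone up to Monte-Carlo noise
})

test_that("forecast_concentrations adds increment and seasonal factors", {
  f <- c(0.00, 0.65, 1.50, 2.40, 3.00, 2.10, 0.57, -1.50,
         -2.97, -2.85, -2.00, -0.90)
  cyc <- seasonal_cycle(f)
  fc <- forecast_concentrations(400.89, 3.28, cyc, two_sd = 0.53,
                                target_year = 2016)
  expect_equal(round(fc$annual_mean, 2), 404.17)
  expect_equal(unname(fc$monthly_means), 404.17 + f)
  expect_equal(mean(fc$monthly_means), fc$annual_mean)

  # the observed 2016 increment lands on the observed annual mean
  fc2 <- forecast_concentrations(400.89, 3.39, cyc)
  expect_equal(round(fc2$annual_mean, 2), 404.28)

  # zero factors: every month equals the annual mean
  fc3 <- forecast_concentrations(400, 2, seasonal_cycle(rep(0, 12)))
  expect_equal(unname(fc3$monthly_means), rep(402, 12))

  # a predict_increment result carries its uncertainty and components along
  m <- increment_model(-0.132, 0.415, 0.237, residual_sd = 0.25)
  fc4 <- forecast_concentrations(400.89, predict_increment(m, 2.02, 10.84),
                                 cyc, target_year = 2016)
  expect_equal(fc4$increment_two_sd, 0.5)
  expect_equal(sum(fc4$components), fc4$increment_central)
})

test_that("model serialization round-trips through plain text", {
  m <- increment_model(-0.132, 0.415, 0.237, residual_sd = 0.265,
                       calibration_years = c(1960, 2014))
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(m, path, provenance = "synthetic run")
  back <- read_model(path)
  expect_equal(coef(back), coef(m))
  expect_equal(back$residual_sd, m$residual_sd)
  expect_equal(back$calibration_years, c(1960L, 2014L))
})

test_that("simulate method draws increments around the model mean", {
  m <- increment_model(0, 0.4, 0.2, residual_sd = 0.25)
  nd <- data.frame(nino = rep(1, 400), emissions = rep(10, 400))
  sims <- simulate(m, nsim = 1, seed = 9, newdata = nd)[[1]]
  expect_equal(mean(sims), 0.4 + 2, tolerance = 0.05)
  expect_equal(sd(sims), 0.25, tolerance = 0.04)
})
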