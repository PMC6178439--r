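# Shared fixture builders (all fixtures are constructed in code).

# Monthly CO2 series with prescribed annual means and a fixed within-year
# offset pattern (zero-sum by construction when `offsets` sums to zero).
series_from_annual_means <- function(years, means, offsets = rep(0, 12)) {
  monthly_series(rep(years, each = 12L), rep(1:12, length(years)),
                 rep(means, each = 12L) + rep(offsets, length(years)),
                 units = "ppm")
}

# Zero-sum sinusoidal offset pattern (exact: sin over a full period of 12
# equally spaced months sums to zero).
sinusoid_offsets <- function(amplitude = 3) {
  amplitude * sin(2 * pi * (1:12) / 12)
}

# Published-era and revised regression coefficients used in worked examples.
alphas_published <- c(-0.132, 0.415, 0.237)
alphas_gcb2016 <- c(-0.080, 0.419, 0.229)
alphas_gcb2017 <- c(0.045, 0.426, 0.214)

# degC member whose Apr(i-1)..Mar(i) window holds the given 12 values.
window_member <- function(target_year, values) {
  wm <- data.frame(year = c(rep(target_year - 1L, 9L), rep(target_year, 3L)),
                   month = c(4:12, 1:3))
  monthly_series(wm$year, wm$month, values, units = "degC")
}
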