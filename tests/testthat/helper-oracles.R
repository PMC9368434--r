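# Independent regression oracles, deliberately not sharing code paths with
# the package internals (which go through lm()).

# two-pass mean-centred simple OLS
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

# brute-force least squares by iteratively refined grid search over
# (slope, intercept); no linear algebra involved
grid_ols_oracle <- function(x, y, half_range = 20, iterations = 25) {
  sse <- function(b0, b1) sum((y - b0 - b1 * x)^2)
  c_slope <- 0; c_int <- 0
  hr_s <- half_range; hr_i <- half_range
  for (it in seq_len(iterations)) {
    slopes <- seq(c_slope - hr_s, c_slope + hr_s, length.out = 41)
    ints <- seq(c_int - hr_i, c_int + hr_i, length.out = 41)
    grid <- expand.grid(b0 = ints, b1 = slopes)
    best <- which.min(mapply(sse, grid$b0, grid$b1))
    c_int <- grid$b0[best]; c_slope <- grid$b1[best]
    hr_s <- hr_s / 8; hr_i <- hr_i / 8
  }
  list(slope = c_slope, intercept = c_int)
}

# noiseless first-order series on the standard sampling schedule
first_order_series <- function(a0 = 9e-4, k = 0.1445,
                               days = c(0, 1, 3, 5, 8, 12, 16, 20, 31),
                               temperature = 288.15, sample_id = "S") {
  oxidation_series(days, a0 * exp(k * days), sample_id = sample_id,
                   temperature = temperature)
}
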