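paper_days <- c(0, 1, 3, 5, 8, 12, 16, 20, 31)

test_that("noiseless exponential growth is fit exactly by the first-order model", {
  s <- first_order_series(a0 = 9e-4, k = 0.1445, days = paper_days)
  f1 <- fit_order(s, 1)
  expect_equal(f1$k, 0.1445, tolerance = 1e-12)
  expect_equal(f1$intercept, log(9e-4), tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  expect_equal(f1$n_points, 9L)
  # the misspecified zero-order fit is strictly worse
  f0 <- fit_order(s, 0)
  expect_lt(f0$r_squared, 1)
  expect_lt(f0$r_squared, f1$r_squared)
})

test_that("all three transformed-scale fits match the independent OLS oracle", {
  set.seed(11)
  for (rep in 1:20) {
    vals <- exp(rnorm(7, 0, 1))  # positive, arbitrary shape
    days <- sort(sample(0:40, 7))
    s <- oxidation_series(days, vals)
    for (n in 0:2) {
      f <- fit_order(s, n)
      y <- switch(as.character(n), "0" = vals, "1" = log(vals),
                  "2" = 1 / vals)
      orc <- ols_oracle(days, y)
      expect_equal(f$slope, orc$slope, tolerance = 1e-10)
      expect_equal(f$intercept, orc$intercept, tolerance = 1e-10)
      expect_equal(f$r_squared, orc$r_squared, tolerance = 1e-10)
      expect_equal(f$k, abs(orc$slope) * (if (n == 2) 1 else sign(orc$slope)),
                   tolerance = 1e-10)
    }
  }
})

test_that("rescaling the time axis rescales k and leaves R^2 unchanged", {
  set.seed(5)
  vals <- 9e-4 * exp(0.15 * paper_days) * exp(rnorm(9, 0, 0.1))
  s_days <- oxidation_series(paper_days, vals)
  s_weeks <- oxidation_series(paper_days * 7, vals)
  f_d <- fit_order(s_days, 1)
  f_w <- fit_order(s_weeks, 1)
  expect_equal(f_w$k, f_d$k / 7, tolerance = 1e-12)
  expect_equal(f_w$r_squared, f_d$r_squared, tolerance = 1e-12)
})

test_that("order selection returns the generating order on noiseless data", {
  # first order
  sel1 <- select_order(first_order_series(k = 0.2))
  expect_identical(sel1$best$order, 1L)
  expect_equal(sel1$best$r_squared, 1, tolerance = 1e-12)
  expect_equal(sel1$best$k, 0.2, tolerance = 1e-12)
  expect_length(sel1$fits, 3L)
  # zero order
  s0 <- oxidation_series(paper_days, 1 + 0.2 * paper_days)
  sel0 <- select_order(s0)
  expect_identical(sel0$best$order, 0L)
  expect_equal(sel0$best$r_squared, 1, tolerance = 1e-12)
  expect_equal(sel0$best$k, 0.2, tolerance = 1e-12)
})

test_that("order selection is robust under realistic multiplicative noise", {
  set.seed(2024)
  picks <- replicate(200, {
    vals <- 7e-4 * exp(0.18 * paper_days) * exp(rnorm(9, 0, 0.15))
    select_order(oxidation_series(paper_days, vals))$best$order
  })
  expect_gte(mean(picks == 1L), 0.90)
})

test_that("invalid series and infeasible transforms fail loudly", {
  expect_error(oxidation_series(c(0, 1), c(1, 2)), "at least 3")
  expect_error(oxidation_series(c(0, 1, 1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(oxidation_series(c(0, 1, 2), c(1, NA, 3)), "finite")
  s <- oxidation_series(c(0, 2, 5), c(1, -0.5, 3))
  expect_error(fit_order(s, 1), "day 2")
  expect_error(fit_order(s, 2), "day 2")
  # with a non-positive value only order 0 remains feasible
  sel <- select_order(s)
  expect_identical(sel$best$order, 0L)
  expect_identical(sel$excluded, 1:2)
})

test_that("tidy CSV round trip preserves the kinetics input schema", {
  trial <- generate_trial(trial_design(noise_sigma = 0, seed = 3))
  path <- tempfile(fileext = ".csv")
  write.csv(trial, path, row.names = FALSE)
  back <- read_oxidation_csv(path)
  expect_equal(back$pv, trial$pv, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  write.csv(trial[, setdiff(names(trial), "pv")], bad, row.names = FALSE)
  expect_error(read_oxidation_csv(bad), "lacks column")
  expect_error(read_oxidation_csv(tempfile()), "not found")
})
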