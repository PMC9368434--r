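test_that("calibration fitting recovers an exact line and matches OLS oracles", {
  cal <- fit_calibration(c(0, 0.2, 0.4), c(0, 0.5, 1.0))
  expect_equal(cal$slope, 2.5, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  # 4-point design against the independent two-pass mean-centred OLS
  conc <- c(0, 0.1, 0.2, 0.4)
  abs510 <- c(0.01, 0.26, 0.49, 1.01)
  cal2 <- fit_calibration(conc, abs510)
  orc <- ols_oracle(conc, abs510)
  expect_equal(cal2$slope, orc$slope, tolerance = 1e-10)
  expect_equal(cal2$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(cal2$r_squared, orc$r_squared, tolerance = 1e-10)

  # and against a brute-force grid-refined least-squares minimiser
  set.seed(42)
  for (rep in 1:5) {
    x <- sort(runif(4, 0, 0.5))
    y <- 2 + 3 * x + rnorm(4, 0, 0.05)
    fit <- fit_calibration(x, y)
    grid <- grid_ols_oracle(x, y)
    expect_equal(fit$slope, grid$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, grid$intercept, tolerance = 1e-9)
  }
})

test_that("degenerate calibration designs are rejected", {
  expect_error(fit_calibration(c(0, 0.2), c(0, 0.5)), "at least 3")
  expect_error(fit_calibration(c(0.2, 0.2, 0.2), c(0.4, 0.5, 0.6)),
               "distinct")
  expect_error(fit_calibration(c(-0.1, 0.2, 0.4), c(0, 0.5, 1)),
               "non-negative")
})

test_that("peroxide value follows the dimensional chain", {
  cal <- fit_calibration(c(0, 0.2, 0.4), c(0, 0.5, 1.0))  # slope 2.5, int 0
  # blank equality -> zero
  expect_equal(peroxide_value(0.3, 0.3, cal, sample_mass = 0.3), 0)
  # frozen hand-expanded chain: conc = 0.25/2.5 = 0.1 mM; 0.1 mM over a
  # 1.5 mL extract = 0.15 umol = 1.5e-4 meq; oil = 0.3 g x 0.36 = 1.08e-4 kg
  pv <- peroxide_value(0.25, 0, cal, sample_mass = 0.3,
                       extract_volume = 1.5, aliquot_volume = 0.2,
                       fat_fraction = 0.36)
  expect_equal(pv, 1.5e-4 / 1.08e-4, tolerance = 1e-12)
  # linear in the blank-corrected absorbance, inverse in sample mass
  pv2 <- peroxide_value(0.5, 0, cal, sample_mass = 0.3,
                        fat_fraction = 0.36)
  expect_equal(pv2, 2 * peroxide_value(0.25, 0, cal, 0.3,
                                       fat_fraction = 0.36))
  pv_half <- peroxide_value(0.25, 0, cal, sample_mass = 0.6,
                            fat_fraction = 0.36)
  expect_equal(pv_half, pv / 2, tolerance = 1e-12)
})

test_that("peroxide value clamps negative concentrations and flags bad curves", {
  cal <- fit_calibration(c(0, 0.2, 0.4), c(0.1, 0.6, 1.1))  # intercept 0.1
  expect_warning(pv <- peroxide_value(0.05, 0, cal, sample_mass = 0.3),
                 "clamped")
  expect_identical(pv, 0)
  expect_warning(peroxide_value(0.1, 0.2, cal, sample_mass = 0.3),
                 "below blank")
  bad <- fit_calibration(c(0, 0.2, 0.4), c(1.0, 0.5, 0.0))  # negative slope
  expect_error(peroxide_value(0.25, 0, bad, sample_mass = 0.3), "positive")
})

test_that("anisidine value implements both formula conventions", {
  expect_equal(as.numeric(p_anisidine_value(0, 0, 1)), 0)
  v <- p_anisidine_value(0.1, 0.2, 1)
  expect_equal(as.numeric(v), 3.5)
  expect_identical(attr(v, "mode"), "aocs")
  v2 <- p_anisidine_value(0.1, 0.2, 1, mode = "verbatim")
  expect_equal(as.numeric(v2), -3.0)   # negative: why verbatim is non-default
  expect_identical(attr(v2, "mode"), "verbatim")
  expect_error(p_anisidine_value(0.1, 0.2, 0), "positive")
})

test_that("TOTOX and moisture identities hold", {
  expect_equal(totox(0, 0), 0)
  expect_equal(totox(1.5, 3.0), 6.0)
  set.seed(3)
  pv <- runif(20, 0, 12)
  expect_equal(totox(pv, 0), 2 * pv)
  panv <- runif(20, 0, 5)
  expect_equal(totox(pv, panv) - panv, 2 * pv, tolerance = 1e-12)

  expect_equal(moisture_fraction(5, 5), 0)
  expect_equal(moisture_fraction(5, 4.9), 2, tolerance = 1e-12)
  expect_error(moisture_fraction(5, 0), "positive")
  expect_error(moisture_fraction(5, 5.1), "exceed")
})

test_that("assay tables are converted to tidy index records", {
  cal <- fit_calibration(c(0, 0.2, 0.4), c(0, 0.5, 1.0))
  assays <- data.frame(
    sample_id = c("A", "A"), temperature_K = 288.15, day = 0,
    assay_type = c("pv", "panv"),
    absorbance_sample = c(0.25, NA), absorbance_blank = c(0, NA),
    sample_mass = c(0.3, NA), fat_fraction = c(0.36, NA),
    a_before = c(NA, 0.1), a_after = c(NA, 0.2), mass = c(NA, 1))
  idx <- indices_from_assays(assays, cal)
  expect_equal(nrow(idx), 1L)
  expect_equal(idx$pv, 1.5e-4 / 1.08e-4, tolerance = 1e-12)
  expect_equal(idx$p_anv, 3.5)
  expect_equal(idx$totox, 2 * idx$pv + idx$p_anv)
  expect_error(indices_from_assays(assays[0, -1], cal), "lacks column")
})
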