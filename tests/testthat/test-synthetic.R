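test_that("Arrhenius extrapolation of k is self-consistent", {
  expect_equal(k_at(0.15, 293.15, 12000, 293.15), 0.15)
  # rounded published parameters stay within rounding error of the line form
  expect_equal(k_at(0.1032, 293, 1742.1 * 8.314, 323),
               exp(3.6748 - 1742.1 / 323), tolerance = 1e-3)
  # a larger Ea steepens the temperature response
  r1 <- k_at(0.1, 293, 12000, 323) / k_at(0.1, 293, 12000, 288)
  r2 <- k_at(0.1, 293, 24000, 323) / k_at(0.1, 293, 24000, 288)
  expect_gt(r2, r1)
  expect_error(k_at(0.1, 293, 12000, -10), "positive")
})

test_that("trial generation is deterministic under a fixed seed", {
  d <- trial_design(seed = 123)
  t1 <- generate_trial(d)
  t2 <- generate_trial(d)
  expect_identical(t1, t2)
  t3 <- generate_trial(trial_design(seed = 124))
  expect_false(identical(t1$pv, t3$pv))
})

test_that("noiseless trials close the loop through kinetics and Arrhenius", {
  d <- trial_design(noise_sigma = 0, seed = 1)
  trial <- generate_trial(d)
  fm <- d$formulations
  for (f in seq_len(nrow(fm))) {
    for (temp in d$temperatures) {
      rows <- trial[trial$sample_id == fm$label[f] &
                      trial$temperature_K == temp, ]
      s <- oxidation_series(rows$day, rows$pv)
      fit <- fit_order(s, 1)
      k_true <- k_at(fm$k_ref[f], d$t_ref, fm$ea[f], temp)
      expect_equal(fit$r_squared, 1, tolerance = 1e-12)
      expect_equal(fit$k, k_true, tolerance = 1e-12 * k_true)
      expect_equal(exp(fit$intercept), fm$a0[f],
                   tolerance = 1e-9 * fm$a0[f])
    }
    # full round trip to (Ea, k0)
    ks <- vapply(d$temperatures, function(temp) {
      rows <- trial[trial$sample_id == fm$label[f] &
                      trial$temperature_K == temp, ]
      fit_order(oxidation_series(rows$day, rows$pv), 1)$k
    }, numeric(1))
    arr <- fit_arrhenius(d$temperatures, ks)
    expect_equal(arr$ea, fm$ea[f], tolerance = 1e-9 * fm$ea[f])
  }
})

test_that("lognormal noise keeps simulated indices strictly positive", {
  d <- trial_design(noise_sigma = 1.5, seed = 42)  # absurdly noisy
  trial <- generate_trial(d)
  expect_true(all(trial$pv > 0))
  expect_true(all(trial$p_anv > 0))
})

test_that("the p-AnV channel is flat while PV grows", {
  d <- trial_design(noise_sigma = 0.1, seed = 9)
  trial <- generate_trial(d)
  one <- trial[trial$sample_id == "NPNS" & trial$temperature_K == 323.15, ]
  expect_gt(max(one$pv) / min(one$pv), 100)      # strong growth
  expect_lt(max(one$p_anv) / min(one$p_anv), 1.3)  # essentially flat
})

test_that("the full-pipeline parameter-recovery experiment meets its bound", {
  # 200 replicates of a single-formulation four-temperature trial at the
  # default noise level; Ea recovered by the ln-scale pipeline
  set.seed(314)
  fm <- data.frame(label = "S", a0 = 7e-4, ea = 12000, k_ref = 0.15)
  rel_err <- replicate(200, {
    d <- trial_design(fm, noise_sigma = 0.1, seed = NULL)
    trial <- generate_trial(d)
    ks <- vapply(d$temperatures, function(temp) {
      rows <- trial[trial$temperature_K == temp, ]
      fit_order(oxidation_series(rows$day, rows$pv), 1)$k
    }, numeric(1))
    abs(fit_arrhenius(d$temperatures, ks)$ea - 12000) / 12000
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("the reference tables expose the published parameters", {
  ref <- spread_reference()
  expect_equal(ref$rates$k[ref$rates$sample == "NPNS-VDCa" &
                             ref$rates$temperature_K == 323.15], 0.2618)
  expect_equal(ref$arrhenius$ea_kJ_mol[ref$arrhenius$sample == "RB"],
               14.4838)
  expect_equal(ref$initial_pv$a0[ref$initial_pv$sample == "NPNS"], 9.0e-4)
  expect_true(ref$initial_pv$measured[ref$initial_pv$sample == "NPNS"])
  # the duplicated RB rate rows are flagged
  dup <- ref$rates[ref$rates$duplicate_flag, ]
  expect_identical(dup$sample, c("RB", "RB"))
  expect_identical(sort(dup$temperature_K), c(303.15, 313.15))
  expect_equal(dup$k[1], dup$k[2])
})
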