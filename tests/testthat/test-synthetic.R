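test_that("synthetic_config validates its fields", {
  expect_error(synthetic_config(true_k = c(A = -0.5)), "positive")
  expect_error(synthetic_config(true_k = c(A = 0.5), true_dispersion = 0),
               "positive")
  expect_error(synthetic_config(true_k = c(A = 0.5), lai_low = 2, lai_high = 1),
               "lai_high")
  expect_error(synthetic_config(true_k = c(A = 0.5), n_per_genotype = 0),
               "positive integer")
  cfg <- synthetic_config(true_k = c(0.4, 0.6))
  expect_identical(names(cfg$true_k), c("G1", "G2"))
})

test_that("generate_lai honors design, bounds and reproducibility", {
  grid_cfg <- synthetic_config(true_k = c(A = 0.5), n_per_genotype = 3,
                               lai_design = "grid", seed = 1)
  expect_equal(generate_lai(grid_cfg), c(0.3, 3.95, 7.6))
  # grid is seed-independent
  grid_cfg2 <- synthetic_config(true_k = c(A = 0.5), n_per_genotype = 3,
                                lai_design = "grid", seed = 999)
  expect_identical(generate_lai(grid_cfg), generate_lai(grid_cfg2))

  unif_cfg <- synthetic_config(true_k = c(A = 0.5), n_per_genotype = 1e4,
                               seed = 7)
  lai <- generate_lai(unif_cfg)
  expect_identical(lai, generate_lai(unif_cfg))
  expect_true(all(lai >= 0.3 & lai <= 7.6))
})

test_that("beta_shapes implements the mean-precision mapping", {
  expect_equal(beta_shapes(0.5, 24), list(shape1 = 12, shape2 = 12))
  expect_equal(beta_shapes(0.9, 10), list(shape1 = 9, shape2 = 1))
  # moment check: implied mean and variance
  sh <- beta_shapes(0.3, 17)
  expect_equal(sh$shape1 / (sh$shape1 + sh$shape2), 0.3)
  expect_equal(sh$shape1 * sh$shape2 /
                 ((sh$shape1 + sh$shape2)^2 * (sh$shape1 + sh$shape2 + 1)),
               0.3 * 0.7 / 18)
  expect_error(beta_shapes(0, 10), "\\(0, 1\\)")
  expect_error(beta_shapes(0.5, -1), "positive")
})

test_that("simulate_dataset reproduces, stays in (0,1) and matches its moments", {
  cfg <- synthetic_config(true_k = c(A = 0.5, B = 0.7), seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_true(all(d1$fpari > 0 & d1$fpari < 1))
  expect_identical(nrow(d1), 72L)

  # vanishing-noise limit: kappa = 1e6 pins draws to the mean curve
  tight <- simulate_dataset(synthetic_config(true_k = c(A = 0.5),
                                             true_dispersion = 1e6,
                                             n_per_genotype = 50,
                                             lai_low = 1.999999,
                                             lai_high = 2.000001, seed = 3))
  expect_true(all(abs(tight$fpari - (1 - exp(-1))) < 1e-2))

  # Monte-Carlo check of the mean and variance at (nearly) fixed LAI = 2
  big <- simulate_dataset(synthetic_config(true_k = c(A = 0.5),
                                           true_dispersion = 12,
                                           n_per_genotype = 1e5,
                                           lai_low = 1.999999,
                                           lai_high = 2.000001, seed = 4))
  mu <- 1 - exp(-1)
  v <- mu * (1 - mu) / 13
  expect_lt(abs(mean(big$fpari) - mu), 3 * sqrt(v / 1e5))
  mc_se_var <- sd((big$fpari - mu)^2) / sqrt(1e5)
  expect_lt(abs(var(big$fpari) - v), 3 * mc_se_var)
})

test_that("normal-family draws are truncated to (0,1) by redraw", {
  cfg <- synthetic_config(true_k = c(A = 0.9), true_dispersion = 0.09,
                          noise_family = "normal", n_per_genotype = 2000,
                          seed = 9)
  d <- simulate_dataset(cfg)
  expect_true(all(d$fpari > 0 & d$fpari < 1))
  # with sd = 0.3 around means up to ~0.999, untruncated draws would exceed 1
  mu <- 1 - exp(-0.9 * d$lai)
  expect_gt(mean(mu + 0.3 > 1), 0)
})

test_that("the maize-study scenario has the documented structure", {
  cfg <- maize_study_config(seed = 1)
  expect_identical(length(cfg$true_k), 7L)
  expect_equal(range(cfg$true_k), c(0.44, 0.71))
  d <- simulate_dataset(cfg)
  expect_identical(nrow(d), 7L * 36L)
  expect_true(all(d$fpari > 0 & d$fpari < 1))
  expect_equal(attr(d, "synthetic_truth")$true_k, cfg$true_k)
})
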