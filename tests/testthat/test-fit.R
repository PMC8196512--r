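test_that("noiseless data on the curve is recovered by every method", {
  k_true <- c(A = 0.45, B = 0.65)
  d0 <- noiseless_dataset(k = k_true)

  lse <- fit_lse(d0, quick_optimizer())
  expect_equal(lse$k_estimates, k_true, tolerance = 1e-6)
  expect_lt(lse$sse, 1e-10)
  expect_null(lse$k_se)
  expect_null(lse$k_interval)

  logt <- fit_logtlm(d0)
  expect_equal(logt$k_estimates, k_true, tolerance = 1e-12)

  mlen <- fit_mle_normal(d0, quick_optimizer())
  expect_equal(mlen$k_estimates, k_true, tolerance = 1e-4)
  # CI width collapses as noise vanishes
  expect_lt(max(mlen$k_interval[, "upper"] - mlen$k_interval[, "lower"]), 1e-2)
})

test_that("fit_lse matches a brute-force grid oracle (J = 1)", {
  d <- toy_beta_dataset(n = 30, seed = 11)
  grid <- seq(0.01, 2, by = 1e-4)
  obj <- vapply(grid, function(k) sse(k, d), numeric(1))
  oracle <- grid[which.min(obj)]
  fit <- fit_lse(d, quick_optimizer())
  expect_lt(abs(fit$k_estimates[["A"]] - oracle), 1e-4)
  expect_error(fit_lse(canopy_dataset(character(0), numeric(0), numeric(0),
                                      genotype_levels = "A")),
               "empty")
})

test_that("fit_mle_normal equals least squares and profiles its variance", {
  for (seed in c(21, 22)) {
    d <- simulate_dataset(synthetic_config(true_k = c(A = 0.5, B = 0.62),
                                           n_per_genotype = 25, seed = seed))
    lse <- fit_lse(d, quick_optimizer())
    mle <- fit_mle_normal(d, quick_optimizer())
    expect_lt(max(abs(lse$k_estimates - mle$k_estimates)), 1e-4)
    # profile MLE of the normal variance is SSE/n
    expect_equal(mle$dispersion_estimate, lse$sse / nrow(d), tolerance = 1e-5)
    expect_true(all(mle$k_interval[, 1] < mle$k_estimates &
                      mle$k_estimates < mle$k_interval[, 2]))
  }
})

test_that("fit_mle_beta recovers simulated truth and guards its support", {
  d <- simulate_dataset(synthetic_config(true_k = c(A = 0.5),
                                         true_dispersion = 12,
                                         n_per_genotype = 300, seed = 31))
  fit <- fit_mle_beta(d, quick_optimizer())
  expect_lt(abs(fit$k_estimates[["A"]] - 0.5), 0.05)
  expect_gt(fit$dispersion_estimate, 0)
  expect_true(fit$converged)

  d_bad <- d
  d_bad$fpari[1] <- 1.0
  expect_error(fit_mle_beta(d_bad, quick_optimizer()), "0 or 1")
})

test_that("fit_logtlm equals the through-origin normal equations", {
  # exact transform inversion on the curve
  d <- canopy_dataset(c("A", "A"), c(1, 2),
                      c(1 - exp(-0.5), 1 - exp(-1)))
  fit <- fit_logtlm(d)
  expect_equal(fit$k_estimates[["A"]], 0.5)

  # closed-form oracle on noisy data
  dn <- toy_beta_dataset(n = 25, seed = 41)
  z <- log(1 - dn$fpari)
  k_hat <- -sum(dn$lai * z) / sum(dn$lai^2)
  rss <- sum((z + k_hat * dn$lai)^2)
  se <- sqrt(rss / (nrow(dn) - 1) / sum(dn$lai^2))
  fitn <- fit_logtlm(dn)
  expect_equal(fitn$k_estimates[["A"]], k_hat)
  expect_equal(fitn$k_se[["A"]], se)
  expect_equal(unname(fitn$k_interval["A", ]),
               unname(k_hat + c(-1, 1) * qt(0.975, nrow(dn) - 1) * se))

  expect_error(fit_logtlm(canopy_dataset(character(0), numeric(0), numeric(0),
                                         genotype_levels = "A")),
               "empty")
})

test_that("per-genotype (joint = FALSE) fits agree with single-genotype fits", {
  d <- simulate_dataset(synthetic_config(true_k = c(A = 0.45, B = 0.7),
                                         n_per_genotype = 30, seed = 51))
  cfg <- quick_optimizer()
  cfg$joint <- FALSE
  split_fit <- fit_mle_beta(d, cfg)
  rows <- d$genotype == "A"
  solo <- fit_mle_beta(canopy_dataset(as.character(d$genotype[rows]),
                                      d$lai[rows], d$fpari[rows]),
                       quick_optimizer())
  expect_equal(split_fit$k_estimates[["A"]], solo$k_estimates[["A"]],
               tolerance = 1e-4)
  expect_identical(length(split_fit$dispersion_estimate), 2L)
})

test_that("Wald standard errors shrink like 1/sqrt(n)", {
  se_at <- function(n) {
    d <- simulate_dataset(synthetic_config(true_k = c(A = 0.5),
                                           true_dispersion = 12,
                                           n_per_genotype = n, seed = 61))
    fit_mle_normal(d, quick_optimizer())$k_se[["A"]]
  }
  ratio <- se_at(100) / se_at(400)
  expect_equal(ratio, 2, tolerance = 0.35)
})

test_that("fit_result validates interval bracketing and naming", {
  expect_error(fit_result("LSE", k_estimates = c(0.5)), "named")
  expect_error(fit_result("MLE_beta", k_estimates = c(A = 0.5),
                          k_interval = cbind(0.6, 0.7)),
               "bracket")
  f <- fit_result("LogTLM", k_estimates = c(A = 0.56),
                  k_interval = cbind(0.51, 0.62))
  expect_identical(rownames(f$k_interval), "A")
})
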