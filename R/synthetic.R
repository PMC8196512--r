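#' Configuration for the synthetic canopy-data generator
#'
#' Describes a simulated field study: per-genotype true extinction
#' coefficients, a shared dispersion, the noise family, and the LAI sampling
#' design.  The generator draws responses around the Beer-Lambert mean
#' `mu = 1 - exp(-k_j * LAI)` either from a beta distribution in
#' mean-precision form (`beta(mu * kappa, (1 - mu) * kappa)`) or from a
#' normal distribution `N(mu, sigma2)` truncated to (0, 1) by redraw.
#'
#' Defaults mirror a typical maize canopy study: LAI spanning 0.3-7.6 and
#' extinction coefficients in the 0.4-0.7 range observed at flowering.
#'
#' @param true_k named (or unnamed) numeric vector of per-genotype extinction
#'   coefficients, all `> 0`; names become genotype labels (default
#'   `G1..GJ`).
#' @param true_dispersion beta precision `kappa` (or variance `sigma2` when
#'   `noise_family = "normal"`), `> 0`.
#' @param noise_family `"beta"` or `"normal"`.
#' @param n_per_genotype observations per genotype, `>= 1`.
#' @param lai_low,lai_high LAI sampling bounds, `0 < lai_low < lai_high`.
#' @param lai_design `"uniform"` (seed-reproducible random draws) or
#'   `"grid"` (deterministic equally spaced values).
#' @param seed integer seed driving one generator stream.
#' @return A `synthetic_config` list.
#' @seealso [simulate_dataset()], [maize_study_config()]
#' @export
synthetic_config <- function(true_k,
                             true_dispersion = 12,
                             noise_family = c("beta", "normal"),
                             n_per_genotype = 36L,
                             lai_low = 0.3,
                             lai_high = 7.6,
                             lai_design = c("uniform", "grid"),
                             seed = 1L) {
  noise_family <- match.arg(noise_family)
  lai_design <- match.arg(lai_design)
  k_values <- as.numeric(true_k)
  names(k_values) <- names(true_k) %||% paste0("G", seq_along(true_k))
  if (length(k_values) < 1L || any(!is.finite(k_values) | k_values <= 0)) {
    stop_domain("`true_k` must be a non-empty vector of positive values")
  }
  check_scalar_positive(true_dispersion, "true_dispersion")
  if (!is.numeric(n_per_genotype) || length(n_per_genotype) != 1L ||
      n_per_genotype < 1L) {
    stop_domain("`n_per_genotype` must be a positive integer")
  }
  check_scalar_positive(lai_low, "lai_low")
  if (!is.finite(lai_high) || lai_high <= lai_low) {
    stop_domain("`lai_high` must exceed `lai_low`")
  }
  structure(list(true_k = k_values,
                 true_dispersion = true_dispersion,
                 noise_family = noise_family,
                 n_per_genotype = as.integer(n_per_genotype),
                 lai_low = lai_low, lai_high = lai_high,
                 lai_design = lai_design,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' A maize-study-like simulation scenario
#'
#' Seven genotypes with true extinction coefficients spanning 0.44-0.71, a
#' shared beta precision of 12 (the mean of the gamma(24, 2) dispersion
#' prior; field studies of this kind report no empirical dispersion, so the
#' value is a stand-in and not an estimate), and uniform LAI sampling over
#' 0.3-7.6.
#'
#' @param seed integer seed.
#' @param n_per_genotype observations per genotype (default 36, the order of
#'   magnitude of a two-experiment split-plot study).
#' @return A `synthetic_config`.
#' @export
maize_study_config <- function(seed = 1L, n_per_genotype = 36L) {
  synthetic_config(
    true_k = c("DK190" = 0.50, "DK2F10" = 0.52, "DK72-10" = 0.44,
               "DK752" = 0.50, "LP 122-2" = 0.61, "P 39 W55" = 0.71,
               "AX 892 MG" = 0.71),
    true_dispersion = 12,
    noise_family = "beta",
    n_per_genotype = n_per_genotype,
    lai_low = 0.3, lai_high = 7.6,
    lai_design = "uniform",
    seed = seed)
}

# Unseeded LAI draws: simulate_dataset() calls this from its already-seeded
# stream so that standalone generate_lai() and in-simulation values coincide.
generate_lai_impl <- function(cfg) {
  n <- cfg$n_per_genotype
  J <- length(cfg$true_k)
  if (cfg$lai_design == "grid") {
    per <- if (n == 1L) (cfg$lai_low + cfg$lai_high) / 2 else
      seq(cfg$lai_low, cfg$lai_high, length.out = n)
    rep(per, times = J)
  } else {
    runif(n * J, min = cfg$lai_low, max = cfg$lai_high)
  }
}

#' Generate LAI values for a synthetic scenario
#'
#' The `"grid"` design returns `n_per_genotype` equally spaced values per
#' genotype and ignores the seed; the `"uniform"` design draws from
#' `U(lai_low, lai_high)` reproducibly from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return numeric vector of length `n_per_genotype * J` (genotype-major
#'   order).
#' @export
generate_lai <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$lai_design == "grid") generate_lai_impl(cfg)
  else with_seed(cfg$seed, generate_lai_impl(cfg))
}

#' Beta shape parameters from mean and precision
#'
#' The mean-precision ("beta regression") parameterization: a beta variate
#' with mean `mu` and precision `kappa` has shapes `a = mu * kappa`,
#' `b = (1 - mu) * kappa` and variance `mu * (1 - mu) / (1 + kappa)`.
#'
#' @param mu mean, strictly in (0, 1) (vectorized).
#' @param kappa precision, `> 0`.
#' @return list with components `shape1` and `shape2`.
#' @examples
#' beta_shapes(0.5, 24) # shapes 12, 12
#' @export
beta_shapes <- function(mu, kappa) {
  if (any(!is.finite(mu) | mu <= 0 | mu >= 1)) {
    stop_domain("`mu` must lie strictly in (0, 1)")
  }
  if (any(!is.finite(kappa) | kappa <= 0)) {
    stop_domain("`kappa` must be positive")
  }
  list(shape1 = mu * kappa, shape2 = (1 - mu) * kappa)
}

#' Simulate a canopy dataset with known truth
#'
#' For each genotype `j` and each LAI value, the response is drawn around the
#' Beer-Lambert mean `mu = 1 - exp(-k_j * LAI)`:
#' * `noise_family = "beta"`: `fpari ~ beta(mu * kappa, (1 - mu) * kappa)`;
#' * `noise_family = "normal"`: `fpari ~ N(mu, sigma2)`, values outside
#'   (0, 1) redrawn so the dataset invariants hold (the *likelihood* a
#'   normal-model fit evaluates remains untruncated).
#'
#' The whole draw is reproducible from `cfg$seed`; the true parameters are
#' attached as `attr(, "synthetic_truth")`.
#'
#' @param cfg a [synthetic_config()].
#' @return A [canopy_dataset()] with `n_per_genotype * J` rows.
#' @examples
#' d <- simulate_dataset(synthetic_config(true_k = c(A = 0.5), seed = 42))
#' attr(d, "synthetic_truth")$true_k
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    lai <- generate_lai_impl(cfg)
    genotype <- rep(names(cfg$true_k), each = cfg$n_per_genotype)
    mu <- -expm1(-cfg$true_k[genotype] * lai)
    y <- if (cfg$noise_family == "beta") {
      shapes <- beta_shapes(mu, cfg$true_dispersion)
      draw_open_unit(function(idx) rbeta(length(idx),
                                         shapes$shape1[idx],
                                         shapes$shape2[idx]),
                     length(mu))
    } else {
      sdev <- sqrt(cfg$true_dispersion)
      draw_open_unit(function(idx) rnorm(length(idx), mu[idx], sdev),
                     length(mu))
    }
    d <- canopy_dataset(genotype = genotype, lai = lai, fpari = y)
    attr(d, "synthetic_truth") <- list(true_k = cfg$true_k,
                                       true_dispersion = cfg$true_dispersion,
                                       noise_family = cfg$noise_family,
                                       seed = cfg$seed)
    d
  })
}

# Rejection sampling onto the open unit interval: redraw any value <= 0 or
# >= 1 (normal tails; beta draws that underflow to exactly 0 or 1).
draw_open_unit <- function(rfun, n, max_rounds = 1000L) {
  y <- rfun(seq_len(n))
  for (round in seq_len(max_rounds)) {
    bad <- which(!is.finite(y) | y <= 0 | y >= 1)
    if (!length(bad)) return(y)
    y[bad] <- rfun(bad)
  }
  stop_domain("truncation redraw failed to converge; noise level is ",
              "incompatible with responses in (0, 1)")
}
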