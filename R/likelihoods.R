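#' Beer-Lambert mean interception curve
#'
#' Expected fraction of intercepted PAR for extinction coefficient `k` and
#' leaf area index `lai`: `1 - exp(-k * lai)`, computed as `-expm1(-k * lai)`
#' for accuracy near zero.  Strictly increasing in `lai` for `k > 0` and
#' bounded in `[0, 1)` for `k >= 0`.
#'
#' @param k extinction coefficient (vectorized).
#' @param lai leaf area index, `>= 0` (vectorized, recycled against `k`).
#' @return expected fPARi values.
#' @examples
#' beer_lambert_mean(0.5, 7.6) # ~0.97763
#' @export
beer_lambert_mean <- function(k, lai) {
  if (any(!is.finite(lai) | lai < 0)) stop_domain("`lai` must be >= 0")
  -expm1(-k * lai)
}

# Per-observation Beer-Lambert mean for a k vector indexed by genotype.
dataset_mean <- function(k_vector, d) {
  J <- n_genotypes(d)
  if (length(k_vector) != J) {
    stop_domain(sprintf("`k_vector` has length %d but the dataset has %d genotype(s)",
                        length(k_vector), J))
  }
  -expm1(-k_vector[as.integer(d$genotype)] * d$lai)
}

#' Sum of squared errors of the Beer-Lambert fit
#'
#' The least-squares loss: `sum((fpari_ij - (1 - exp(-k_j * lai_ij)))^2)`
#' over all observations, with one `k_j` per genotype.
#'
#' @param k_vector numeric vector of per-genotype coefficients, length equal
#'   to the number of genotypes (dataset index order).
#' @param d a [canopy_dataset()].
#' @return non-negative scalar.
#' @export
sse <- function(k_vector, d) {
  mu <- dataset_mean(k_vector, d)
  sum((d$fpari - mu)^2)
}

#' Normal log-likelihood of the Beer-Lambert model
#'
#' `sum(dnorm(fpari_ij, mean = 1 - exp(-k_j * lai_ij), sd = sqrt(sigma2),
#' log = TRUE))`.  The normal density has unbounded support, so no domain
#' restriction applies to `fpari` beyond the dataset invariants.
#'
#' @inheritParams sse
#' @param sigma2 residual variance, `> 0`.
#' @return log-likelihood (scalar).
#' @export
normal_loglik <- function(k_vector, sigma2, d) {
  check_scalar_positive(sigma2, "sigma2")
  mu <- dataset_mean(k_vector, d)
  sum(dnorm(d$fpari, mean = mu, sd = sqrt(sigma2), log = TRUE))
}

#' Beta log-likelihood of the Beer-Lambert model
#'
#' Mean-precision beta likelihood:
#' `fpari_ij ~ beta(mu_ij * kappa, (1 - mu_ij) * kappa)` with
#' `mu_ij = 1 - exp(-k_j * lai_ij)`.  Returns `-Inf` when any `mu_ij` falls
#' outside (0, 1) (e.g. a non-positive trial `k`), since the density is then
#' undefined — an "impossible parameter" value rather than an error.
#'
#' @inheritParams sse
#' @param kappa beta precision, `> 0`.
#' @return log-likelihood (scalar), possibly `-Inf`.
#' @export
beta_loglik <- function(k_vector, kappa, d) {
  check_scalar_positive(kappa, "kappa")
  if (nrow(d) == 0L) return(0)
  if (any(d$fpari <= 0 | d$fpari >= 1)) {
    stop_domain("beta likelihood undefined: `fpari` touches 0 or 1")
  }
  mu <- dataset_mean(k_vector, d)
  if (any(!is.finite(mu) | mu <= 0 | mu >= 1)) return(-Inf)
  sum(dbeta(d$fpari, shape1 = mu * kappa, shape2 = (1 - mu) * kappa,
            log = TRUE))
}

#' Central finite-difference Hessian
#'
#' Symmetrized second-derivative matrix of a scalar objective, used to turn a
#' maximized log-likelihood into approximate variances (inverse observed
#' information).  Step sizes are relative: `h_i = step * max(1, |x_i|)`.
#'
#' @param objective function of a numeric parameter vector returning a scalar.
#' @param point numeric vector at which to differentiate.
#' @param step relative step size, default `1e-4`.
#' @return a symmetric `length(point)` square matrix.
#' @examples
#' numeric_hessian(function(x) (x - 0.5)^2, 0.5) # ~2
#' @export
numeric_hessian <- function(objective, point, step = 1e-4) {
  p <- length(point)
  h <- step * pmax(1, abs(point))
  f0 <- objective(point)
  if (!is.finite(f0)) stop_domain("objective non-finite at `point`")
  H <- matrix(NA_real_, p, p)
  shift <- function(i, amount) {
    x <- point
    x[i] <- x[i] + amount
    x
  }
  for (i in seq_len(p)) {
    fp <- objective(shift(i, h[i]))
    fm <- objective(shift(i, -h[i]))
    if (!is.finite(fp) || !is.finite(fm)) {
      stop_domain("objective non-finite in the stencil at coordinate ", i)
    }
    H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
    for (j in seq_len(i - 1L)) {
      fpp <- objective(shift(j, h[j]) + (shift(i, h[i]) - point))
      fpm <- objective(shift(j, -h[j]) + (shift(i, h[i]) - point))
      fmp <- objective(shift(j, h[j]) + (shift(i, -h[i]) - point))
      fmm <- objective(shift(j, -h[j]) + (shift(i, -h[i]) - point))
      if (any(!is.finite(c(fpp, fpm, fmp, fmm)))) {
        stop_domain("objective non-finite in the stencil at coordinates ",
                    i, ",", j)
      }
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}
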