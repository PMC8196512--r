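#' Optimizer settings for the least-squares and likelihood fits
#'
#' All optimizer-based methods use a multi-start quasi-Newton (BFGS) search:
#' per-genotype starting values for `k` are drawn uniformly from
#' `(start_low, start_high)` — the range reported for extinction coefficients
#' in the maize literature — and the best of `n_starts` local optima is kept.
#' Dispersion parameters are optimized on the log scale so positivity needs
#' no constrained optimizer; their start is a method-of-moments value from
#' the residuals of the best least-squares fit.
#'
#' @param n_starts number of random restarts, `>= 1` (default 10).
#' @param start_low,start_high bounds for the random `k` starts (default
#'   0.2 and 0.8).
#' @param seed seed for the start draws (default 1; `NULL` uses the current
#'   RNG stream).
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @param maxit iteration cap per start.
#' @param joint if `TRUE` (default) one model is fitted with a single
#'   dispersion shared across genotypes; if `FALSE` each genotype is fitted
#'   independently with its own dispersion.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(n_starts = 10L, start_low = 0.2, start_high = 0.8,
                             seed = 1L, reltol = 1e-12, maxit = 500L,
                             joint = TRUE) {
  if (n_starts < 1L) stop_domain("`n_starts` must be >= 1")
  if (!(start_low < start_high)) stop_domain("`start_low` must be < `start_high`")
  structure(list(n_starts = as.integer(n_starts),
                 start_low = start_low, start_high = start_high,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 reltol = reltol, maxit = as.integer(maxit),
                 joint = isTRUE(joint)),
            class = "optimizer_config")
}

#' Assemble a fit result
#'
#' The common container returned by every `fit_*()` method: per-genotype
#' point estimates with (method permitting) standard errors and 95%
#' intervals, the shared dispersion estimate, the maximized log-likelihood
#' (or the minimized SSE for least squares), and fit metadata.  Exposed so
#' that externally obtained estimates (e.g. published tables) can be fed into
#' [comparison_report()].
#'
#' @param method one of `"LSE"`, `"MLE_normal"`, `"MLE_beta"`, `"LogTLM"`,
#'   `"Bayes_beta"`.
#' @param k_estimates named numeric vector of per-genotype estimates.
#' @param k_se named numeric vector of standard errors, or `NULL` (least
#'   squares carries no uncertainty by construction).
#' @param k_interval two-column matrix (`lower`, `upper`) of 95% intervals,
#'   rows named by genotype, or `NULL`.
#' @param dispersion_estimate `sigma2` or `kappa` estimate, or `NULL`.
#' @param loglik maximized log-likelihood, or `NULL`.
#' @param sse minimized sum of squared errors (least squares), or `NULL`.
#' @param converged logical convergence flag.
#' @param n_obs,n_genotypes dataset dimensions.
#' @param config_echo list echoing the settings that produced the fit.
#' @return A `canopy_fit` object.
#' @export
fit_result <- function(method, k_estimates, k_se = NULL, k_interval = NULL,
                       dispersion_estimate = NULL, loglik = NULL, sse = NULL,
                       converged = TRUE, n_obs = NA_integer_,
                       n_genotypes = length(k_estimates),
                       config_echo = list()) {
  method <- match.arg(method,
                      c("LSE", "MLE_normal", "MLE_beta", "LogTLM", "Bayes_beta"))
  if (is.null(names(k_estimates))) {
    stop_domain("`k_estimates` must be named by genotype")
  }
  if (!is.null(k_interval)) {
    k_interval <- as.matrix(k_interval)
    colnames(k_interval) <- c("lower", "upper")
    rownames(k_interval) <- names(k_estimates)
    ok <- is.na(k_interval[, 1]) | is.na(k_interval[, 2]) |
      (k_interval[, 1] < k_estimates & k_estimates < k_interval[, 2])
    if (!all(ok)) {
      stop_domain("interval must bracket the estimate for every genotype")
    }
  }
  structure(list(method = method,
                 k_estimates = k_estimates,
                 k_se = k_se,
                 k_interval = k_interval,
                 dispersion_estimate = dispersion_estimate,
                 loglik = loglik,
                 sse = sse,
                 converged = isTRUE(converged),
                 n_obs = n_obs,
                 n_genotypes = n_genotypes,
                 config_echo = config_echo),
            class = "canopy_fit")
}

#' @export
print.canopy_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<canopy_fit: %s> %d genotype(s), %s observations%s\n",
              x$method, x$n_genotypes, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = round(x$k_estimates, digits))
  if (!is.null(x$k_se)) tab$se <- round(x$k_se, digits)
  if (!is.null(x$k_interval)) {
    tab$`95% interval` <- sprintf("(%.*f, %.*f)", digits,
                                  x$k_interval[, 1], digits, x$k_interval[, 2])
  }
  print(tab)
  if (!is.null(x$dispersion_estimate)) {
    cat("dispersion:", format(x$dispersion_estimate, digits = digits + 1), "\n")
  }
  if (!is.null(x$loglik)) cat("log-likelihood:", format(x$loglik), "\n")
  if (!is.null(x$sse)) cat("SSE:", format(x$sse), "\n")
  invisible(x)
}

# Multi-start BFGS minimization.  `objective` maps the full parameter vector
# to a scalar to MINIMIZE; `make_start` maps a k-start vector to a full
# start.  Returns the best converged optimum (or best attempt with
# converged = FALSE if all starts fail).
multi_start_optim <- function(objective, J, cfg, make_start = identity) {
  starts <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_starts), function(s) {
      runif(J, cfg$start_low, cfg$start_high)
    })
  })
  # Guard the objective: errors or non-finite values during a line search
  # become a large plateau instead of aborting the start.
  safe_objective <- function(par) {
    val <- tryCatch(objective(par), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  best <- NULL
  any_converged <- FALSE
  for (k0 in starts) {
    par0 <- make_start(k0)
    res <- tryCatch(
      optim(par0, safe_objective, method = "BFGS",
            control = list(reltol = cfg$reltol, maxit = cfg$maxit,
                           ndeps = rep(1e-6, length(par0)))),
      error = function(e) NULL)
    if (is.null(res)) next
    converged <- res$convergence == 0L
    any_converged <- any_converged || converged
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$this_converged <- converged
    }
  }
  if (is.null(best)) {
    stop_domain("optimization failed from every start; check the data")
  }
  best$converged_any <- any_converged
  best
}

#' Least-squares estimate of the extinction coefficients
#'
#' Minimizes [sse()] over one `k` per genotype with multi-start BFGS.  Least
#' squares makes no distributional assumption, so the result carries no
#' standard errors and no intervals — only point estimates and the achieved
#' SSE.
#'
#' @param d a [canopy_dataset()] with at least one observation.
#' @param cfg an [optimizer_config()].
#' @return A [fit_result()] with method `"LSE"`.
#' @export
fit_lse <- function(d, cfg = optimizer_config()) {
  if (nrow(d) == 0L) stop_domain("empty dataset")
  J <- n_genotypes(d)
  best <- multi_start_optim(function(k) sse(k, d), J, cfg)
  k_hat <- setNames(best$par, genotypes(d))
  fit_result("LSE", k_estimates = k_hat, sse = best$value,
             converged = best$converged_any,
             n_obs = nrow(d), n_genotypes = J,
             config_echo = unclass(cfg))
}

# Shared machinery for the two likelihood fits.  `loglik_fun(k, disp)` is the
# log-likelihood with dispersion on the NATURAL scale; optimization runs over
# (k_1..k_J, log disp).  Wald SEs come from the inverse finite-difference
# Hessian of the negative log-likelihood at the optimum.
fit_mle_generic <- function(d, cfg, method, loglik_fun, disp_start) {
  if (nrow(d) == 0L) stop_domain("empty dataset")
  counts <- table(d$genotype)
  if (any(counts < 2L)) {
    stop_domain("each genotype needs >= 2 observations for a likelihood fit")
  }
  if (!cfg$joint) {
    return(fit_mle_per_genotype(d, cfg, method, loglik_fun, disp_start))
  }
  J <- n_genotypes(d)
  negll <- function(par) {
    val <- loglik_fun(par[seq_len(J)], exp(par[J + 1L]))
    if (!is.finite(val)) return(1e10)
    -val
  }
  best <- multi_start_optim(negll, J, cfg,
                            make_start = function(k0) c(k0, log(disp_start)))
  k_hat <- setNames(best$par[seq_len(J)], genotypes(d))
  disp_hat <- exp(best$par[J + 1L])
  loglik_hat <- -best$value

  # Observed information in the optimization coordinates (k, log disp): the
  # k-block of the inverse is invariant to how the dispersion is
  # parameterized, and the log scale keeps the stencil well-conditioned even
  # when the dispersion estimate is extreme (near-noiseless data).
  se <- rep(NA_real_, J)
  H <- tryCatch(
    numeric_hessian(function(par) {
      val <- loglik_fun(par[seq_len(J)], exp(par[J + 1L]))
      if (!is.finite(val)) return(NA_real_)
      -val
    }, best$par),
    error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V)[seq_len(J)] > 0)) {
      se <- sqrt(diag(V)[seq_len(J)])
    }
  }
  if (anyNA(se)) {
    warning("Hessian not invertible at the optimum; standard errors unavailable",
            call. = FALSE)
  }
  se <- setNames(se, genotypes(d))
  z <- 1.959964
  ci <- cbind(lower = k_hat - z * se, upper = k_hat + z * se)
  fit_result(method, k_estimates = k_hat, k_se = se, k_interval = ci,
             dispersion_estimate = disp_hat, loglik = loglik_hat,
             converged = best$converged_any, n_obs = nrow(d),
             n_genotypes = J, config_echo = unclass(cfg))
}

# Independent per-genotype fits (config flag joint = FALSE): each genotype
# gets its own dispersion; results are concatenated.
fit_mle_per_genotype <- function(d, cfg, method, loglik_fun, disp_start) {
  fits <- lapply(genotypes(d), function(g) {
    rows <- d$genotype == g
    sub <- canopy_dataset(as.character(d$genotype[rows]), d$lai[rows],
                          d$fpari[rows])
    sub_ll <- if (identical(method, "MLE_normal")) {
      function(k, disp) normal_loglik(k, disp, sub)
    } else {
      function(k, disp) beta_loglik(k, disp, sub)
    }
    fit_mle_generic(sub, within_cfg_joint(cfg), method, sub_ll, disp_start)
  })
  k_hat <- unlist(lapply(fits, `[[`, "k_estimates"))
  se <- unlist(lapply(fits, `[[`, "k_se"))
  ci <- do.call(rbind, lapply(fits, `[[`, "k_interval"))
  fit_result(method, k_estimates = k_hat, k_se = se, k_interval = ci,
             dispersion_estimate = setNames(
               vapply(fits, `[[`, numeric(1), "dispersion_estimate"),
               genotypes(d)),
             loglik = sum(vapply(fits, `[[`, numeric(1), "loglik")),
             converged = all(vapply(fits, `[[`, logical(1), "converged")),
             n_obs = nrow(d), n_genotypes = n_genotypes(d),
             config_echo = c(unclass(cfg), list(joint = FALSE)))
}

within_cfg_joint <- function(cfg) {
  cfg$joint <- TRUE
  cfg
}

# Method-of-moments dispersion starts from the residuals of the best LSE fit.
moment_starts <- function(d, cfg) {
  lse <- fit_lse(d, cfg)
  s2 <- lse$sse / nrow(d)
  mu <- dataset_mean(lse$k_estimates, d)
  kappa <- mean(mu * (1 - mu)) / max(s2, 1e-12) - 1
  list(sigma2 = max(s2, 1e-8),
       kappa = min(max(kappa, 0.5), 1e6),
       lse = lse)
}

#' Maximum likelihood fit with a normal likelihood
#'
#' Maximizes [normal_loglik()] jointly over `(k_1..k_J, log sigma2)` with
#' multi-start BFGS.  Standard errors are the square roots of the diagonal of
#' the inverse observed-information matrix (finite-difference Hessian of the
#' negative log-likelihood at the optimum); 95% intervals are Wald,
#' `estimate +/- 1.959964 * SE`.  The point estimates coincide with least
#' squares — the normal likelihood is monotone in the SSE — which the test
#' suite asserts to `1e-4`.
#'
#' @inheritParams fit_lse
#' @return A [fit_result()] with method `"MLE_normal"`; `dispersion_estimate`
#'   is the variance `sigma2` (which equals `SSE / n` at the optimum).
#' @export
fit_mle_normal <- function(d, cfg = optimizer_config()) {
  starts <- moment_starts(d, cfg)
  fit_mle_generic(d, cfg, "MLE_normal",
                  function(k, disp) normal_loglik(k, disp, d),
                  disp_start = starts$sigma2)
}

#' Maximum likelihood fit with a beta likelihood
#'
#' Maximizes [beta_loglik()] jointly over `(k_1..k_J, log kappa)` with
#' multi-start BFGS; uncertainty machinery as in [fit_mle_normal()].  The
#' beta likelihood restricts the response to (0, 1), matching the support of
#' a proportion, so — unlike the normal model — its predictive distribution
#' cannot produce values outside the unit interval.
#'
#' @inheritParams fit_lse
#' @return A [fit_result()] with method `"MLE_beta"`; `dispersion_estimate`
#'   is the beta precision `kappa`.
#' @export
fit_mle_beta <- function(d, cfg = optimizer_config()) {
  if (any(d$fpari <= 0 | d$fpari >= 1)) {
    stop_domain("beta likelihood undefined: `fpari` touches 0 or 1")
  }
  starts <- moment_starts(d, cfg)
  fit_mle_generic(d, cfg, "MLE_beta",
                  function(k, disp) beta_loglik(k, disp, d),
                  disp_start = starts$kappa)
}

#' Log-transformed linear model fit
#'
#' The Beer-Lambert curve linearizes as `log(1 - fPARi) = -k * LAI`, a
#' through-origin regression.  Each genotype is fitted independently by
#' ordinary least squares of `z = log(1 - fpari)` on `lai` with no intercept:
#' in closed form `k_hat = -sum(lai * z) / sum(lai^2)`.  Standard errors and
#' 95% confidence intervals follow standard through-origin linear-model
#' theory on the log scale (residual variance with `n - 1` degrees of
#' freedom, t quantile).  Note the estimate is optimal for the *log-scale*
#' model; back-transformed observation-level predictions (see
#' [predict_fpari()]) are generally worse than those of the nonlinear fits.
#'
#' @inheritParams fit_lse
#' @return A [fit_result()] with method `"LogTLM"` (no dispersion estimate;
#'   log-scale residual variance is echoed in `config_echo`).
#' @export
fit_logtlm <- function(d) {
  if (nrow(d) == 0L) stop_domain("empty dataset")
  if (any(d$fpari >= 1)) stop_domain("log(1 - fpari) undefined at fpari = 1")
  gts <- genotypes(d)
  z_all <- log1p(-d$fpari)
  est <- se <- sigma2_log <- setNames(numeric(length(gts)), gts)
  df_resid <- setNames(integer(length(gts)), gts)
  for (g in gts) {
    rows <- d$genotype == g
    if (sum(rows) < 2L) {
      stop_domain("genotype ", g, " has < 2 observations; no residual degrees of freedom")
    }
    z <- z_all[rows]
    lai <- d$lai[rows]
    sxx <- sum(lai^2)
    est[g] <- -sum(lai * z) / sxx          # through-origin normal equation
    rss <- sum((z + est[g] * lai)^2)
    df_resid[g] <- sum(rows) - 1L
    sigma2_log[g] <- rss / df_resid[g]
    se[g] <- sqrt(sigma2_log[g] / sxx)
  }
  tq <- qt(0.975, df_resid)
  # a perfect (zero-residual) fit has se = 0; widen by machine epsilon so the
  # interval still brackets the estimate
  half <- pmax(tq * se, 4 * .Machine$double.eps * pmax(1, abs(est)))
  ci <- cbind(lower = est - half, upper = est + half)
  fit_result("LogTLM", k_estimates = est, k_se = se, k_interval = ci,
             loglik = NULL, converged = TRUE, n_obs = nrow(d),
             n_genotypes = length(gts),
             config_echo = list(log_scale_residual_variance = sigma2_log,
                                df_residual = df_resid))
}
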