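#' Predict fPARi from a fitted model
#'
#' Every method predicts through the Beer-Lambert mean,
#' `1 - exp(-k_hat_j * lai)`.  For the log-transformed linear model this *is*
#' the back-transformation of its log-scale predictions to the observation
#' level, which makes mean-squared errors comparable across methods.  Mean
#' -function predictions always lie in `[0, 1)` regardless of method.
#'
#' @param fit a [fit_result()].
#' @param lai numeric vector of LAI values, `>= 0`.
#' @param genotype a single genotype label present in the fit.
#' @return predicted fPARi values.
#' @export
predict_fpari <- function(fit, lai, genotype) {
  stopifnot(inherits(fit, "canopy_fit"))
  if (length(genotype) != 1L || !genotype %in% names(fit$k_estimates)) {
    stop_domain("unknown genotype: ", paste(genotype, collapse = ", "))
  }
  beer_lambert_mean(fit$k_estimates[[genotype]], lai)
}

#' @export
predict.canopy_fit <- function(object, newdata, ...) {
  if (!all(c("genotype", "lai") %in% names(newdata))) {
    stop_domain("`newdata` needs columns genotype and lai")
  }
  g <- as.character(newdata$genotype)
  missing_g <- setdiff(unique(g), names(object$k_estimates))
  if (length(missing_g)) {
    stop_domain("fit does not cover genotype(s): ",
                paste(missing_g, collapse = ", "))
  }
  beer_lambert_mean(object$k_estimates[g], newdata$lai)
}

#' Observation-level mean squared error
#'
#' `mean((predicted - observed)^2)`.
#'
#' @param predicted,observed equal-length numeric vectors, `n >= 1`.
#' @return non-negative scalar.
#' @export
mse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop_domain("`predicted` and `observed` must have equal length")
  }
  if (length(predicted) == 0L) stop_domain("empty input")
  mean((predicted - observed)^2)
}

#' Fraction of values outside the unit interval
#'
#' A prediction-validity check: proportions live in `[0, 1]`, but a normal
#' predictive distribution can place mass outside it.  Mean-function
#' predictions always give 0; apply this to predictive *draws*
#' (`mu_hat + noise`) to quantify how often a model predicts the impossible.
#'
#' @param values numeric vector, `n >= 1`.
#' @return proportion of entries `< 0` or `> 1`.
#' @export
out_of_range_fraction <- function(values) {
  if (length(values) == 0L) stop_domain("empty input")
  mean(values < 0 | values > 1)
}

#' Residual summary of a fit on a dataset
#'
#' Residuals are `predicted - observed` at the observation level (log-scale
#' fits are back-transformed first, see [predict_fpari()]).
#'
#' @param fit a [fit_result()] covering every genotype in `d`.
#' @param d a [canopy_dataset()].
#' @return list with `mean`, `sd`, `min`, `max`, `mse`, `n`.
#' @export
residual_summary <- function(fit, d) {
  pred <- predict(fit, d)
  r <- pred - d$fpari
  list(mean = mean(r), sd = sd(r), min = min(r), max = max(r),
       mse = mse(pred, d$fpari), n = length(r))
}

#' Assemble a multi-method comparison report
#'
#' Collates fits of the same dataset into one report: per-genotype estimates
#' with standard errors and 95% intervals, per-method observation-level MSE
#' and residual summaries, the out-of-range fraction of the mean-function
#' predictions (always 0 — recorded to contrast with predictive draws), and
#' each estimate's relative magnitude versus the log-transformed linear
#' model's estimate for the same genotype, `100 * k_method / k_LogTLM`
#' (percent; full precision retained, rounding happens only at printing).
#'
#' `dataset` may be omitted when only estimate bookkeeping is wanted (e.g.
#' comparing externally published estimates); metric fields are then `NA`.
#'
#' @param fits named list of [fit_result()] objects (names are ignored; each
#'   fit's `method` field labels it).
#' @param dataset optional [canopy_dataset()] the fits were obtained from.
#' @param failures optional named list of error messages for methods whose
#'   fit failed.
#' @return A `comparison_report` with components `estimates` (long
#'   data.frame), `metrics` (per-method data.frame), `relative_magnitude`
#'   (method x genotype matrix, percent), `failures`.
#' @export
comparison_report <- function(fits, dataset = NULL, failures = list()) {
  stopifnot(length(fits) >= 1L)
  methods <- vapply(fits, `[[`, character(1), "method")
  if (anyDuplicated(methods)) stop_domain("duplicate method in `fits`")
  names(fits) <- methods

  estimates <- do.call(rbind, lapply(fits, function(f) {
    data.frame(method = f$method,
               genotype = names(f$k_estimates),
               estimate = unname(f$k_estimates),
               se = if (is.null(f$k_se)) NA_real_ else unname(f$k_se),
               lower = if (is.null(f$k_interval)) NA_real_ else f$k_interval[, 1],
               upper = if (is.null(f$k_interval)) NA_real_ else f$k_interval[, 2],
               row.names = NULL)
  }))

  gts <- unique(estimates$genotype)
  rel <- matrix(NA_real_, nrow = length(fits), ncol = length(gts),
                dimnames = list(methods, gts))
  if ("LogTLM" %in% methods) {
    ref <- fits[["LogTLM"]]$k_estimates
    for (m in methods) {
      common <- intersect(names(fits[[m]]$k_estimates), names(ref))
      rel[m, common] <- 100 * fits[[m]]$k_estimates[common] / ref[common]
    }
  }

  metrics <- do.call(rbind, lapply(fits, function(f) {
    if (is.null(dataset)) {
      return(data.frame(method = f$method, mse = NA_real_,
                        residual_mean = NA_real_, residual_sd = NA_real_,
                        residual_min = NA_real_, residual_max = NA_real_,
                        out_of_range_fraction = NA_real_, row.names = NULL))
    }
    rs <- residual_summary(f, dataset)
    data.frame(method = f$method, mse = rs$mse,
               residual_mean = rs$mean, residual_sd = rs$sd,
               residual_min = rs$min, residual_max = rs$max,
               out_of_range_fraction =
                 out_of_range_fraction(predict(f, dataset)),
               row.names = NULL)
  }))

  structure(list(estimates = estimates, metrics = metrics,
                 relative_magnitude = rel, failures = failures,
                 n_obs = if (is.null(dataset)) NA_integer_ else nrow(dataset)),
            class = "comparison_report")
}

#' Fit and compare several estimation methods on one dataset
#'
#' Fits each requested method on the same dataset and assembles a
#' [comparison_report()].  Individual fit failures are recorded in the
#' report's `failures` field rather than aborting the comparison.
#'
#' @param d a [canopy_dataset()].
#' @param methods subset of `c("LSE", "MLE_normal", "MLE_beta", "LogTLM",
#'   "Bayes_beta")`.
#' @param optimizer an [optimizer_config()] shared by the optimizer methods.
#' @param priors a [prior_spec()] for the Bayesian fit.
#' @param mcmc an [mcmc_control()] for the Bayesian fit.
#' @return A `comparison_report`.
#' @export
compare_methods <- function(d,
                            methods = c("LSE", "MLE_normal", "MLE_beta",
                                        "LogTLM", "Bayes_beta"),
                            optimizer = optimizer_config(),
                            priors = prior_spec(),
                            mcmc = mcmc_control()) {
  methods <- match.arg(methods, several.ok = TRUE)
  fitters <- list(
    LSE = function() fit_lse(d, optimizer),
    MLE_normal = function() fit_mle_normal(d, optimizer),
    MLE_beta = function() fit_mle_beta(d, optimizer),
    LogTLM = function() fit_logtlm(d),
    Bayes_beta = function() fit_bayes_beta(d, priors, mcmc))
  fits <- list()
  failures <- list()
  for (m in methods) {
    res <- tryCatch(fitters[[m]](), error = function(e) e)
    if (inherits(res, "error")) failures[[m]] <- conditionMessage(res)
    else fits[[m]] <- res
  }
  if (!length(fits)) {
    stop_domain("every requested method failed: ",
                paste(sprintf("%s (%s)", names(failures), unlist(failures)),
                      collapse = "; "))
  }
  comparison_report(fits, dataset = d, failures = failures)
}

#' @export
print.comparison_report <- function(x, digits = 2, ...) {
  cat("<comparison_report>\n\nEstimates (95% intervals):\n")
  print(estimates_table(x, digits = digits), right = FALSE)
  has_metrics <- !all(is.na(x$metrics$mse))
  if (has_metrics) {
    cat("\nPredictive metrics (observation level):\n")
    m <- x$metrics
    m[-1] <- lapply(m[-1], signif, digits = digits + 2)
    print(m, row.names = FALSE)
  }
  if (any(is.finite(x$relative_magnitude))) {
    cat("\nRelative magnitude vs LogTLM (%):\n")
    print(round(x$relative_magnitude))
  }
  if (length(x$failures)) {
    cat("\nFailed methods:\n")
    for (m in names(x$failures)) cat("  ", m, ": ", x$failures[[m]], "\n", sep = "")
  }
  invisible(x)
}

# Wide genotype x method table of "estimate (lower-upper)" strings.
estimates_table <- function(report, digits = 2) {
  est <- report$estimates
  gts <- unique(est$genotype)
  methods <- unique(est$method)
  tab <- matrix("", nrow = length(gts), ncol = length(methods),
                dimnames = list(gts, methods))
  for (i in seq_len(nrow(est))) {
    cell <- formatC(est$estimate[i], digits = digits, format = "f")
    if (!is.na(est$lower[i])) {
      cell <- sprintf("%s (%s-%s)", cell,
                      formatC(est$lower[i], digits = digits, format = "f"),
                      formatC(est$upper[i], digits = digits, format = "f"))
    }
    tab[est$genotype[i], est$method[i]] <- cell
  }
  as.data.frame(tab)
}

#' Serialize a comparison report
#'
#' `report_to_json()` writes the whole report as one JSON document;
#' `report_to_csv()` writes two CSVs into `dir`: `estimates.csv` (genotype x
#' method grid of "estimate (lower-upper)" cells) and `metrics.csv`
#' (per-method MSE, residual summary and out-of-range fraction).
#'
#' @param report a `comparison_report`.
#' @param path,dir output locations.
#' @return the written path(s), invisibly.
#' @export
report_to_json <- function(report, path) {
  payload <- list(estimates = report$estimates,
                  metrics = report$metrics,
                  relative_magnitude_percent = report$relative_magnitude,
                  failures = report$failures,
                  n_obs = report$n_obs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_to_csv <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  est_path <- file.path(dir, "estimates.csv")
  met_path <- file.path(dir, "metrics.csv")
  tab <- estimates_table(report)
  tab <- cbind(genotype = rownames(tab), tab)
  write.csv(tab, est_path, row.names = FALSE)
  write.csv(report$metrics, met_path, row.names = FALSE)
  invisible(c(est_path, met_path))
}
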