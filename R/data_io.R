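#' Construct a canopy light-interception dataset
#'
#' A `canopy_dataset` is a `data.frame` with one row per observation and three
#' required columns: `genotype` (a factor whose levels follow first appearance
#' order), `lai` (leaf area index, dimensionless, strictly positive) and
#' `fpari` (fraction of intercepted photosynthetically active radiation,
#' strictly inside the open interval (0, 1) — the beta likelihood and the
#' log transform are undefined at the endpoints).  Extra columns passed via
#' `...` are preserved as passthrough metadata.
#'
#' Every genotype appearing in the observations must have at least two rows:
#' no uncertainty estimate is possible from a single observation.  An empty
#' dataset (zero rows) is only allowed when `genotype_levels` is supplied
#' explicitly; it is useful for prior-predictive checks where the likelihood
#' contributes nothing.
#'
#' @param genotype character or factor vector of genotype labels.
#' @param lai numeric vector of leaf area index values, `> 0`.
#' @param fpari numeric vector of intercepted-PAR fractions in `(0, 1)`.
#' @param ... additional equal-length columns carried through unchanged.
#' @param genotype_levels optional character vector fixing the genotype index
#'   order (defaults to first appearance order).
#' @return A `canopy_dataset` (also a `data.frame`).
#' @examples
#' d <- canopy_dataset(c("A", "A", "B", "B"), c(1, 2, 1, 2),
#'                     c(0.4, 0.6, 0.35, 0.55))
#' n_genotypes(d)
#' @export
canopy_dataset <- function(genotype, lai, fpari, ..., genotype_levels = NULL) {
  genotype <- as.character(genotype)
  lai <- as.numeric(lai)
  fpari <- as.numeric(fpari)
  n <- length(genotype)
  if (length(lai) != n || length(fpari) != n) {
    stop_domain("`genotype`, `lai` and `fpari` must have equal length")
  }
  if (n == 0L && is.null(genotype_levels)) {
    stop_domain("empty dataset: no observations and no `genotype_levels` given")
  }
  levels <- genotype_levels %||% unique(genotype)
  if (!all(genotype %in% levels)) {
    stop_domain("`genotype_levels` does not cover all observed labels: ",
                paste(setdiff(genotype, levels), collapse = ", "))
  }
  d <- data.frame(genotype = factor(genotype, levels = levels),
                  lai = lai, fpari = fpari,
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) d[[nm]] <- extra[[nm]]
  class(d) <- c("canopy_dataset", "data.frame")
  assert_canopy_dataset(d)
  d
}

# Validation shared by the constructor and the readers.  Errors name rows so
# that bad field records are locatable.
assert_canopy_dataset <- function(d) {
  bad_lai <- which(!is.finite(d$lai) | d$lai <= 0)
  if (length(bad_lai)) {
    stop_domain("`lai` must be finite and > 0; offending row(s): ",
                paste(bad_lai, collapse = ", "))
  }
  bad_f <- which(!is.finite(d$fpari) | d$fpari <= 0 | d$fpari >= 1)
  if (length(bad_f)) {
    stop_domain("`fpari` must lie strictly in (0, 1); offending row(s): ",
                paste(bad_f, collapse = ", "))
  }
  counts <- table(factor(as.character(d$genotype),
                         levels = unique(as.character(d$genotype))))
  singletons <- names(counts)[counts < 2L]
  if (length(singletons)) {
    stop_domain("each genotype needs at least 2 observations; offending: ",
                paste(singletons, collapse = ", "))
  }
  invisible(d)
}

#' @rdname canopy_dataset
#' @param d a `canopy_dataset`.
#' @export
genotypes <- function(d) levels(d$genotype)

#' @rdname canopy_dataset
#' @export
n_genotypes <- function(d) length(levels(d$genotype))

#' Read a canopy dataset from a delimited text file
#'
#' Reads a comma-separated file (header row, `.` decimal mark, UTF-8) and
#' validates it into a [canopy_dataset()].  Column headers are remappable via
#' `column_map`, so files using e.g. `hybrid`/`LAI`/`fIPAR` work unchanged.
#' Row order and any unmapped columns are preserved.
#'
#' @param path path to a CSV file with a header row.
#' @param column_map named character vector mapping the logical names
#'   `genotype`, `lai`, `fpari` to the file's column headers.
#' @param endpoint_policy,epsilon forwarded to [validate_dataset()].
#' @return A validated `canopy_dataset`, genotype index in first-appearance
#'   order.
#' @seealso [write_canopy_table()]
#' @export
read_canopy_table <- function(path,
                              column_map = c(genotype = "genotype",
                                             lai = "lai", fpari = "fpari"),
                              endpoint_policy = c("reject", "clamp"),
                              epsilon = 1e-6) {
  endpoint_policy <- match.arg(endpoint_policy)
  required <- c("genotype", "lai", "fpari")
  if (!all(required %in% names(column_map))) {
    stop_domain("`column_map` must name columns for: ",
                paste(setdiff(required, names(column_map)), collapse = ", "))
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(column_map[required]), names(raw))
  if (length(missing_cols)) {
    stop_domain("input file lacks mapped column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop_domain("empty dataset: ", path)
  for (logical_name in c("lai", "fpari")) {
    col <- raw[[column_map[[logical_name]]]]
    parsed <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(parsed) & !is.na(col))
    if (length(bad)) {
      stop_domain(sprintf("non-numeric `%s` value in row(s): %s",
                          logical_name, paste(bad, collapse = ", ")))
    }
    raw[[column_map[[logical_name]]]] <- parsed
  }
  extras <- raw[, setdiff(names(raw), unname(column_map[required])),
                drop = FALSE]
  d <- data.frame(genotype = factor(as.character(raw[[column_map[["genotype"]]]]),
                                    levels = unique(as.character(raw[[column_map[["genotype"]]]]))),
                  lai = raw[[column_map[["lai"]]]],
                  fpari = raw[[column_map[["fpari"]]]])
  for (nm in names(extras)) d[[nm]] <- extras[[nm]]
  class(d) <- c("canopy_dataset", "data.frame")
  validate_dataset(d, endpoint_policy = endpoint_policy, epsilon = epsilon)
}

#' Write a canopy dataset to CSV
#'
#' Inverse of [read_canopy_table()]: comma-separated, `.` decimal, UTF-8,
#' full double precision so that read/write round-trips are lossless.
#'
#' @param d a `canopy_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_canopy_table <- function(d, path) {
  out <- as.data.frame(d)
  out$genotype <- as.character(out$genotype)
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate (and optionally repair) dataset domain constraints
#'
#' The beta likelihood has support on the open interval (0, 1) and the log
#' transform diverges at `fpari = 1`, so endpoint observations must either be
#' rejected or clamped.  Under `"reject"` (the default — field fPARi rarely
#' touches the boundary) any violation is an error listing the offending rows.
#' Under `"clamp"`, `fpari` is moved into `[epsilon, 1 - epsilon]` with one
#' warning reporting how many rows were touched.  `lai <= 0` is always an
#' error: clamping applies to `fpari` only.
#'
#' `validate_dataset(reject)` is idempotent; the clamp policy is idempotent
#' after one application.
#'
#' @param d a `canopy_dataset` or a data.frame with columns `genotype`,
#'   `lai`, `fpari`.
#' @param endpoint_policy `"reject"` or `"clamp"`.
#' @param epsilon clamping margin, default `1e-6`.
#' @return The validated `canopy_dataset`.
#' @export
validate_dataset <- function(d, endpoint_policy = c("reject", "clamp"),
                             epsilon = 1e-6) {
  endpoint_policy <- match.arg(endpoint_policy)
  if (!all(c("genotype", "lai", "fpari") %in% names(d))) {
    stop_domain("`d` must have columns genotype, lai, fpari")
  }
  if (!is.factor(d$genotype)) {
    d$genotype <- factor(as.character(d$genotype),
                         levels = unique(as.character(d$genotype)))
  }
  if (!inherits(d, "canopy_dataset")) class(d) <- c("canopy_dataset", "data.frame")
  if (endpoint_policy == "clamp") {
    check_scalar_positive(epsilon, "epsilon")
    out_of_range <- which(is.finite(d$fpari) &
                            (d$fpari < epsilon | d$fpari > 1 - epsilon))
    if (length(out_of_range)) {
      d$fpari[out_of_range] <- pmin(pmax(d$fpari[out_of_range], epsilon),
                                    1 - epsilon)
      warning(sprintf("clamped fpari to [%g, 1-%g] in %d row(s)",
                      epsilon, epsilon, length(out_of_range)), call. = FALSE)
    }
  }
  assert_canopy_dataset(d)
  d
}

#' Leaf area from lamina length and width
#'
#' Maize lamina area is well approximated by a rescaled rectangle,
#' `alpha * length * width`, with shape factor `alpha = 0.75` by default.
#'
#' @param length_cm lamina length, `> 0` (cm).
#' @param width_cm maximum lamina width, `> 0` (cm).
#' @param alpha dimensionless shape factor, default `0.75`.
#' @return leaf area in cm^2 (vectorized).
#' @examples
#' leaf_area(80, 9) # 540 cm^2
#' @export
leaf_area <- function(length_cm, width_cm, alpha = 0.75) {
  if (any(!is.finite(length_cm) | length_cm <= 0) ||
      any(!is.finite(width_cm) | width_cm <= 0)) {
    stop_domain("`length_cm` and `width_cm` must be positive")
  }
  if (any(!is.finite(alpha) | alpha <= 0)) stop_domain("`alpha` must be positive")
  alpha * length_cm * width_cm
}

#' Fraction of intercepted PAR from sensor readings
#'
#' `1 - par_bottom / par_top`, the complement of canopy transmittance
#' measured with paired quantum-sensor readings above and below the canopy.
#'
#' @param par_top PAR flux at the canopy top, `> 0`.
#' @param par_bottom PAR flux below the canopy, in `[0, par_top]`.
#' @return proportion intercepted, in `[0, 1]` (vectorized).
#' @examples
#' fpari_from_par(2000, 100) # 0.95
#' @export
fpari_from_par <- function(par_top, par_bottom) {
  if (any(!is.finite(par_top) | par_top <= 0)) {
    stop_domain("`par_top` must be positive")
  }
  if (any(!is.finite(par_bottom) | par_bottom < 0)) {
    stop_domain("`par_bottom` must be non-negative")
  }
  if (any(par_bottom > par_top)) {
    stop_domain("inconsistent measurement: `par_bottom` exceeds `par_top`")
  }
  1 - par_bottom / par_top
}

#' Leaf area index from per-plant leaf area and stand density
#'
#' @param mean_leaf_area_per_plant mean leaf area per plant (m^2), `> 0`.
#' @param stand_density plants per m^2 of ground, `> 0`.
#' @return LAI, m^2 leaf per m^2 ground (vectorized).
#' @examples
#' lai_from_plants(0.6, 9) # 5.4
#' @export
lai_from_plants <- function(mean_leaf_area_per_plant, stand_density) {
  if (any(!is.finite(mean_leaf_area_per_plant) | mean_leaf_area_per_plant <= 0) ||
      any(!is.finite(stand_density) | stand_density <= 0)) {
    stop_domain("both arguments must be positive")
  }
  mean_leaf_area_per_plant * stand_density
}

#' @export
print.canopy_dataset <- function(x, ...) {
  cat(sprintf("<canopy_dataset> %d observations, %d genotype(s)\n",
              nrow(x), n_genotypes(x)))
  if (nrow(x)) {
    cat(sprintf("  LAI in [%.3g, %.3g]; fPARi in [%.3g, %.3g]\n",
                min(x$lai), max(x$lai), min(x$fpari), max(x$fpari)))
  }
  NextMethod()
}
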