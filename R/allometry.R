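## Allometric size correction: log-log regression residuals against a size
## proxy (humeral length), the standard device for isolating shape variation
## from body-size scaling before ordination.

#' Log-log residual size correction
#'
#' For each variable, regresses `log10(variable)` on `log10(size proxy)` by
#' ordinary least squares across all specimens with both values present, and
#' returns the residuals: size-independent shape variation. Fossil and extant
#' specimens are pooled in one fit per variable by default; alternatively the
#' fit can use extant specimens only, with fossils projected onto the extant
#' allometry.
#'
#' @param d a [mfs_data] dataset
#' @param variables measurement names to correct (default the nine
#'   osteological variables, everything except the proxy)
#' @param size_proxy measurement used as the size regressor (default `"HL"`)
#' @param base logarithm base (default 10; the residual structure is
#'   identical for any base)
#' @param pool_fossils if `FALSE`, regressions are fitted on extant specimens
#'   only and fossil residuals are computed against that fit
#' @return An object of class `residual_matrix`: list with `values`
#'   (specimen x variable matrix of residuals, NA where the variable is
#'   missing), `specimen_ids`, `variable_names`, `regressor`, `slopes`,
#'   `intercepts`, `base`, `n_used`.
#' @details Specimens missing a variable are dropped from that variable's
#'   regression with a warning. Fewer than 3 complete specimens for a
#'   variable is an error naming the variable.
#' @export
log_size_residuals <- function(d, variables = OSTEO_VARS, size_proxy = "HL",
                               base = 10, pool_fossils = TRUE) {
  d <- derive_ful(d)
  proxy <- d[[size_proxy]]
  if (is.null(proxy)) mfs_schema_error(sprintf("unknown size proxy '%s'", size_proxy))
  lx <- log(proxy, base)
  extant <- d$group %in% HABITS
  vals <- matrix(NA_real_, nrow(d), length(variables),
                 dimnames = list(d$specimen_id, variables))
  slopes <- intercepts <- stats::setNames(numeric(length(variables)), variables)
  n_used <- stats::setNames(integer(length(variables)), variables)
  dropped <- character()
  for (v in variables) {
    y <- d[[v]]
    if (is.null(y)) mfs_schema_error(sprintf("unknown variable '%s'", v))
    ok <- !is.na(y) & !is.na(proxy)
    fit_rows <- ok & (pool_fossils | extant)
    if (sum(fit_rows) < 3)
      mfs_error(sprintf("fewer than 3 complete specimens for variable %s", v),
                "mfs_insufficient_data_error")
    if (any(!ok)) dropped <- c(dropped, d$specimen_id[!ok])
    fit <- stats::lm(log(y[fit_rows], base) ~ lx[fit_rows])
    b <- unname(stats::coef(fit))
    intercepts[v] <- b[1]; slopes[v] <- b[2]
    vals[ok, v] <- log(y[ok], base) - (b[1] + b[2] * lx[ok])
    n_used[v] <- sum(fit_rows)
  }
  if (length(dropped))
    warning(sprintf("specimens missing values, dropped from some regressions: %s",
                    paste(unique(dropped), collapse = ", ")), call. = FALSE)
  structure(list(values = vals, specimen_ids = d$specimen_id,
                 variable_names = variables, regressor = size_proxy,
                 slopes = slopes, intercepts = intercepts, base = base,
                 n_used = n_used, pool_fossils = pool_fossils),
            class = "residual_matrix")
}

#' Column z-standardization
#'
#' Centers each column to mean 0 and scales to standard deviation 1
#' (denominator n - 1), the standardization applied to residuals and
#' functional variables before ordination.
#'
#' @param x numeric matrix, or a `residual_matrix` object
#' @return Matrix of the same shape with attributes `center` and `scale`.
#' @export
zscore <- function(x) {
  if (inherits(x, "residual_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 2) mfs_domain_error("z-standardization needs at least 2 rows")
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  zero <- !is.na(sdv) & sdv == 0
  if (any(zero))
    mfs_error(sprintf("zero-variance column(s): %s",
                      paste(colnames(x)[zero], collapse = ", ")),
              "mfs_degenerate_column_error")
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  attr(z, "center") <- mu
  attr(z, "scale") <- sdv
  z
}
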