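## The morphofunctional space: a PCA ordination of either the size-corrected
## osteological block or the functional (index + lever) block, with convex
## hulls delimiting the region occupied by each extant locomotor habit.
## Fossils are projected as points and never contribute hulls.

#' Principal component decomposition with a deterministic sign convention
#'
#' Thin wrapper around the covariance eigenstructure of an
#' already-standardized matrix: loadings are unit-norm eigenvectors, scores
#' the centered data projected on them, and the sign of each axis is fixed so
#' that the largest-magnitude loading entry is positive, making outputs
#' reproducible across platforms.
#'
#' @param x numeric matrix (specimens x variables), finite entries
#' @return List with `scores`, `loadings`, `sdev`, `variance_explained`
#'   (percent per axis, non-increasing) and `center`.
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) mfs_domain_error("PCA needs at least 2 specimens")
  if (!all(is.finite(x))) mfs_validation_error("PCA input must be finite (no missing values)")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
       variance_explained = ve, center = p$center)
}

#' Convex hulls of habit groups in a 2-D ordination
#'
#' One hull per extant locomotor habit over the first two score columns,
#' vertices in counterclockwise order; habits with one or two specimens
#' return their points as a degenerate hull. Fossils get no hull.
#'
#' @param scores matrix with at least 2 columns (PC1, PC2)
#' @param groups group label per row
#' @return Named list, habit -> vertex matrix (columns PC1, PC2).
#' @export
habit_hulls <- function(scores, groups) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  hulls <- list()
  for (h in intersect(HABITS, unique(groups))) {
    pts <- scores[groups == h, , drop = FALSE]
    if (nrow(pts) <= 2) {
      hulls[[h]] <- pts
    } else {
      idx <- grDevices::chull(pts[, 1], pts[, 2])
      hulls[[h]] <- orient_ccw(pts[idx, , drop = FALSE])
    }
  }
  hulls
}

orient_ccw <- function(v) {
  n <- nrow(v)
  if (n < 3) return(v)
  j <- c(2:n, 1)
  area2 <- sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])
  if (area2 < 0) v[rev(seq_len(n)), , drop = FALSE] else v
}

#' Point-in-polygon test
#'
#' Ray-crossing test used by the hull invariants; points on an edge count as
#' inside.
#'
#' @param pt numeric length-2 point
#' @param poly vertex matrix (2 columns)
#' @return logical
#' @export
point_in_hull <- function(pt, poly) {
  n <- nrow(poly)
  if (n == 1) return(isTRUE(all(abs(pt - poly[1, ]) < 1e-9)))
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment check
    d <- abs((xj - xi) * (pt[2] - yi) - (yj - yi) * (pt[1] - xi))
    if (d < 1e-9 &&
        pt[1] >= min(xi, xj) - 1e-9 && pt[1] <= max(xi, xj) + 1e-9 &&
        pt[2] >= min(yi, yj) - 1e-9 && pt[2] <= max(yi, yj) + 1e-9)
      return(TRUE)
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

#' Fit a morphofunctional space
#'
#' The central fitting function of the package. For `block = "osteological"`
#' the nine linear osteological variables are size-corrected by log-log
#' regression residuals against humeral length ([log_size_residuals()]),
#' z-standardized, and ordinated by PCA. For `block = "functional"` the
#' seven percentage indices and three mechanical-advantage models are
#' z-standardized directly (they are dimensionless, so no size correction)
#' and ordinated. Convex hulls are computed per extant locomotor habit on
#' the first two axes.
#'
#' @param d a [mfs_data] dataset
#' @param block `"osteological"` or `"functional"`
#' @param variables variable names to ordinate; defaults to the canonical
#'   nine (osteological) or ten (functional) variables
#' @param size_proxy,base,pool_fossils passed to [log_size_residuals()]
#'   (osteological block only)
#' @param chain_angle_deg passed to [ma_profile()] (functional block only)
#' @return An object of class `mfs`: list with `scores`, `loadings`,
#'   `variance_explained`, `cumulative_variance` (two leading axes, percent),
#'   `hulls`, `specimen_id`, `group`, `focal`, `block`, `allometry` (the
#'   `residual_matrix`, osteological block), `z_center`, `z_scale`,
#'   `pca_center`, `dropped` (specimens excluded for missing variables),
#'   `contains_estimate`, and `call`. Supports `print()`, `summary()`,
#'   `plot()`, `predict()` and `residuals()`.
#' @examples
#' d <- make_study_like_dataset(seed = 1)
#' fit <- mfs(d, block = "functional")
#' fit$cumulative_variance
#' @export
mfs <- function(d, block = c("osteological", "functional"), variables = NULL,
                size_proxy = "HL", base = 10, pool_fossils = TRUE,
                chain_angle_deg = 180) {
  block <- match.arg(block)
  d <- derive_ful(d)
  est <- vapply(estimated_fields(d), function(x) length(x) > 0, logical(1))
  allom <- NULL
  if (block == "osteological") {
    variables <- variables %||% OSTEO_VARS
    allom <- log_size_residuals(d, variables, size_proxy, base, pool_fossils)
    raw <- allom$values
  } else {
    variables <- variables %||% FUNCTIONAL_VARS
    ft <- functional_table(d)
    raw <- as.matrix(ft[, variables, drop = FALSE])
    rownames(raw) <- d$specimen_id
  }
  complete <- stats::complete.cases(raw)
  dropped <- d$specimen_id[!complete]
  if (length(dropped))
    warning(sprintf("specimens dropped from the %s morphospace (incomplete variables): %s",
                    block, paste(dropped, collapse = ", ")), call. = FALSE)
  raw <- raw[complete, , drop = FALSE]
  if (nrow(raw) < 3) mfs_domain_error("morphospace needs at least 3 complete specimens")
  z <- zscore(raw)
  p <- pca_fit(z)
  groups <- d$group[complete]
  structure(list(
    scores = p$scores, loadings = p$loadings,
    variance_explained = p$variance_explained,
    cumulative_variance = sum(p$variance_explained[1:min(2, length(p$variance_explained))]),
    hulls = habit_hulls(p$scores, groups),
    specimen_id = d$specimen_id[complete], group = groups,
    focal = d$focal[complete], block = block, variables = variables,
    allometry = allom, z_center = attr(z, "center"), z_scale = attr(z, "scale"),
    pca_center = p$center, sdev = p$sdev, dropped = dropped,
    contains_estimate = est[complete], chain_angle_deg = chain_angle_deg,
    call = match.call()), class = "mfs")
}

#' Osteological morphospace
#'
#' Shorthand for `mfs(d, block = "osteological", ...)`.
#' @inheritParams mfs
#' @param ... passed to [mfs()]
#' @return An `mfs` object.
#' @export
osteological_morphospace <- function(d, ...) mfs(d, block = "osteological", ...)

#' Functional morphospace
#'
#' Shorthand for `mfs(d, block = "functional", ...)`.
#' @inheritParams osteological_morphospace
#' @return An `mfs` object.
#' @export
functional_morphospace <- function(d, ...) mfs(d, block = "functional", ...)

#' @export
print.mfs <- function(x, ...) {
  cat(sprintf("Morphofunctional space (%s block)\n", x$block))
  cat(sprintf("  %d specimens, %d variables\n", nrow(x$scores), length(x$variables)))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% (cumulative %.2f%%)\n",
              x$variance_explained[1], x$variance_explained[2],
              x$cumulative_variance))
  if (length(x$dropped))
    cat(sprintf("  dropped (incomplete): %s\n", paste(x$dropped, collapse = ", ")))
  invisible(x)
}

#' @export
summary.mfs <- function(object, n_axes = min(4, ncol(object$scores)), ...) {
  out <- list(block = object$block,
              variance = data.frame(
                axis = colnames(object$scores)[1:n_axes],
                variance_explained = object$variance_explained[1:n_axes],
                cumulative = cumsum(object$variance_explained)[1:n_axes]),
              loadings = object$loadings[, 1:n_axes, drop = FALSE],
              n = nrow(object$scores),
              groups = table(object$group))
  class(out) <- "summary.mfs"
  out
}

#' @export
print.summary.mfs <- function(x, ...) {
  cat(sprintf("Morphofunctional space (%s block), %d specimens\n\n", x$block, x$n))
  print(x$variance, row.names = FALSE, digits = 4)
  cat("\nLoadings:\n")
  print(round(x$loadings, 3))
  cat("\nSpecimens per group:\n")
  print(x$groups)
  invisible(x)
}

#' @export
residuals.mfs <- function(object, ...) {
  if (is.null(object$allometry))
    mfs_domain_error("residuals are defined for the osteological block only")
  object$allometry$values
}

#' Project new specimens into a fitted morphospace
#'
#' Applies the stored transformations of the fit (allometric coefficients,
#' z-centering and scaling, PCA center and loadings) to new specimens without
#' refitting, returning their scores in the fitted space.
#'
#' @param object a fitted `mfs` object
#' @param newdata a [mfs_data] dataset
#' @param ... unused
#' @return Score matrix (specimens x axes) for the complete specimens of
#'   `newdata`.
#' @export
predict.mfs <- function(object, newdata, ...) {
  newdata <- derive_ful(newdata)
  if (object$block == "osteological") {
    a <- object$allometry
    lx <- log(newdata[[a$regressor]], a$base)
    raw <- sapply(a$variable_names, function(v)
      log(newdata[[v]], a$base) - (a$intercepts[v] + a$slopes[v] * lx))
    raw <- matrix(raw, nrow = nrow(newdata),
                  dimnames = list(newdata$specimen_id, a$variable_names))
  } else {
    ft <- functional_table(newdata, chain_angle_deg = object$chain_angle_deg)
    raw <- as.matrix(ft[, object$variables, drop = FALSE])
    rownames(raw) <- newdata$specimen_id
  }
  keep <- stats::complete.cases(raw)
  raw <- raw[keep, , drop = FALSE]
  z <- sweep(sweep(raw, 2, object$z_center, "-"), 2, object$z_scale, "/")
  sweep(z, 2, object$pca_center, "-") %*% object$loadings
}

#' Plot a morphofunctional space
#'
#' PC1 x PC2 scatter with habit convex hulls; fossils are plotted as filled
#' triangles and the focal specimen as a star.
#'
#' @param x an `mfs` object
#' @param axes which two score columns to draw
#' @param ... passed to [graphics::plot()]
#' @return `x`, invisibly.
#' @export
plot.mfs <- function(x, axes = c(1, 2), ...) {
  sc <- x$scores[, axes, drop = FALSE]
  cols <- stats::setNames(grDevices::hcl.colors(length(HABITS), "Dark 3"), HABITS)
  lab <- sprintf("PC%d (%.1f%%)", axes, x$variance_explained[axes])
  graphics::plot(sc, type = "n", xlab = lab[1], ylab = lab[2],
                 main = sprintf("Morphofunctional space (%s)", x$block), ...)
  for (h in names(x$hulls)) {
    v <- x$hulls[[h]]
    if (nrow(v) >= 3)
      graphics::polygon(v, border = cols[h],
                        col = grDevices::adjustcolor(cols[h], 0.15))
    else if (nrow(v) == 2) graphics::lines(v, col = cols[h])
  }
  extant <- x$group %in% HABITS
  graphics::points(sc[extant, , drop = FALSE], pch = 19, col = cols[x$group[extant]])
  graphics::points(sc[!extant & !x$focal, , drop = FALSE], pch = 17)
  if (any(x$focal))
    graphics::points(sc[x$focal, , drop = FALSE], pch = 8, cex = 1.6, col = "red")
  graphics::legend("topright", bty = "n", pch = c(rep(19, length(HABITS)), 17, 8),
                   col = c(cols, "black", "red"),
                   legend = c(HABITS, "fossil", "focal"), cex = 0.8)
  invisible(x)
}
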