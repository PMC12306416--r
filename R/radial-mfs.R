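## Triangular radial morphofunctional space: the three lever models as radial
## axes normalized to the dataset maxima, concentric rings at 20% increments,
## and a shaded performance envelope for a reference habit (extant diggers).

RADIAL_AXES <- c("MAe", "MAe_MTCIII", "MAw")
## axis orientation: classical elbow model at the top, elbow+manus model on
## the right, wrist model on the left
RADIAL_ANGLES_DEG <- c(MAe = 90, MAe_MTCIII = 330, MAw = 210)

#' Build a radial morphofunctional space
#'
#' Normalizes each specimen's three mechanical-advantage values by the
#' maximum recorded on that axis across the whole dataset, and derives a
#' per-axis performance envelope for a reference habit.
#'
#' @param ma lever table as returned by [ma_profile()] (columns
#'   `specimen_id`, `group`, `MAe`, `MAe_MTCIII`, `MAw`), or a [mfs_data]
#'   dataset (converted via [ma_profile()])
#' @param envelope_group habit whose occupied band is shaded (default
#'   `"digger"`, the extant scratch-diggers)
#' @param envelope_stat `"range"` (per-axis min-max over the envelope group;
#'   default, the weakest assumption) or `"mean_se"` (mean +/- one standard
#'   error)
#' @return Object of class `radial_mfs`: list with `axes`, `axis_max`
#'   (percent), `rings` (fractions 0.2 ... 1), `points` (specimen x axis
#'   matrix of normalized coordinates in (0, 1]), `groups`, `envelope`
#'   (axis -> c(low, high), normalized), `envelope_group`. Specimens missing
#'   any of the three values are excluded.
#' @export
radial_mfs <- function(ma, envelope_group = "digger",
                       envelope_stat = c("range", "mean_se")) {
  envelope_stat <- match.arg(envelope_stat)
  if (inherits(ma, "mfs_data")) ma <- ma_profile(ma)
  m <- as.matrix(ma[, RADIAL_AXES])
  rownames(m) <- ma$specimen_id
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  groups <- ma$group[keep]
  if (nrow(m) == 0)
    mfs_domain_error("no specimen with all three MA values")
  axis_max <- apply(m, 2, max)
  pts <- sweep(m, 2, axis_max, "/")
  env_rows <- groups == envelope_group
  if (!any(env_rows))
    mfs_error(sprintf("envelope group '%s' is empty", envelope_group),
              "mfs_config_error")
  env <- apply(pts[env_rows, , drop = FALSE], 2, function(x) {
    if (envelope_stat == "range") c(low = min(x), high = max(x))
    else {
      se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
      c(low = mean(x) - se, high = mean(x) + se)
    }
  })
  structure(list(axes = RADIAL_AXES, axis_max = axis_max,
                 rings = seq(0.2, 1, by = 0.2), points = pts, groups = groups,
                 envelope = env, envelope_group = envelope_group,
                 envelope_stat = envelope_stat),
            class = "radial_mfs")
}

#' @export
print.radial_mfs <- function(x, ...) {
  cat("Radial morphofunctional space (3 lever axes)\n")
  cat(sprintf("  axis maxima: %s\n",
              paste(sprintf("%s %.2f%%", x$axes, x$axis_max), collapse = ", ")))
  cat(sprintf("  %d specimens; envelope: %s (%s)\n", nrow(x$points),
              x$envelope_group, x$envelope_stat))
  invisible(x)
}

#' Plot-ready geometry for a radial morphofunctional space
#'
#' Converts the normalized radial space into 2-D polygon coordinates:
#' axis vertices at 90 (top), 330 (right) and 210 (left) degrees, ring
#' triangles at each 20% increment, the envelope band (outer and inner
#' triangles), and one triangle per specimen.
#'
#' @param r a `radial_mfs` object
#' @return List with `axis_ends` (unit vectors per axis), `rings` (fraction
#'   -> 3x2 vertex matrix), `envelope` (`outer`, `inner` vertex matrices),
#'   and `triangles` (specimen -> 3x2 vertex matrix).
#' @export
radial_plot_data <- function(r) {
  ang <- RADIAL_ANGLES_DEG[r$axes] * pi / 180
  u <- cbind(x = cos(ang), y = sin(ang))
  tri <- function(frac) u * frac  # frac: per-axis radius, recycled or length 3
  list(axis_ends = u,
       rings = stats::setNames(lapply(r$rings, tri), sprintf("%.0f%%", 100 * r$rings)),
       envelope = list(outer = tri(r$envelope["high", ]),
                       inner = tri(r$envelope["low", ])),
       triangles = stats::setNames(
         lapply(seq_len(nrow(r$points)), function(i) tri(r$points[i, ])),
         rownames(r$points)))
}

#' Plot a radial morphofunctional space
#'
#' Draws the 20%-increment rings, the reference-habit envelope band, and one
#' triangle per specimen (focal/others distinguished by color).
#'
#' @param x a `radial_mfs` object
#' @param highlight specimen ids drawn in red (default none)
#' @param ... unused
#' @return `x`, invisibly.
#' @export
plot.radial_mfs <- function(x, highlight = character(), ...) {
  pd <- radial_plot_data(x)
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Radial morphofunctional space")
  for (ring in pd$rings)
    graphics::polygon(ring, border = "grey70", lty = 3)
  graphics::polygon(pd$envelope$outer, col = grDevices::adjustcolor("grey40", 0.3),
                    border = NA)
  graphics::polygon(pd$envelope$inner, col = "white", border = NA)
  for (ring in pd$rings)
    graphics::polygon(ring, border = "grey70", lty = 3)
  for (nm in names(pd$triangles))
    graphics::polygon(pd$triangles[[nm]],
                      border = if (nm %in% highlight) "red" else "grey30",
                      lwd = if (nm %in% highlight) 2 else 1)
  lab_pos <- pd$axis_ends * 1.15
  graphics::text(lab_pos, labels = c("MAe", "MAe + MTCIII-L", "MAw"))
  invisible(x)
}
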