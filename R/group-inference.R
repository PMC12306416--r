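## Habit-level inference on the functional variables: one-way ANOVA across
## extant locomotor habits, Tukey-Kramer HSD post hocs summarized as a
## compact letter display, one-sample t-tests comparing the focal fossil's
## single value against each habit, and Welch t-tests comparing the fossil
## sample against each habit. No correction is applied across variables
## (each variable is tested at alpha on its own).

#' One-way fixed-effects ANOVA
#'
#' Classical decomposition; a thin wrapper around [stats::aov()] returning
#' the quantities used by the habit comparison.
#'
#' @param values numeric vector
#' @param groups group label per value
#' @return List with `F`, `df_between` (k - 1), `df_within` (N - k), `p`.
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) mfs_domain_error("ANOVA needs at least 2 groups")
  if (length(values) <= nlevels(g))
    mfs_domain_error("ANOVA needs total N greater than the number of groups")
  if (stats::var(values) == 0)
    mfs_domain_error("degenerate ANOVA: all values identical")
  tab <- stats::anova(stats::aov(values ~ g))
  Fv <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (tab$`Mean Sq`[2] == 0) { # zero within-group variance, non-zero between
    Fv <- Inf
    p <- 0
  }
  list(F = Fv, df_between = tab$Df[1], df_within = tab$Df[2], p = p)
}

#' Tukey-Kramer honestly-significant-difference post hocs
#'
#' All pairwise group comparisons with studentized-range adjusted p-values
#' via [stats::TukeyHSD()]; the Tukey-Kramer form accommodates unequal group
#' sizes and reduces to classical Tukey HSD for balanced designs.
#'
#' @inheritParams one_way_anova
#' @param conf_level confidence level for the interval columns
#' @return data.frame with `group1`, `group2`, `diff` (mean of group2 minus
#'   mean of group1), `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  g <- factor(groups)
  if (stats::var(values) == 0)
    mfs_domain_error("degenerate post hoc: all values identical")
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, "", 2),
             group2 = vapply(pairs, `[`, "", 1),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise tests
#'
#' Insert-and-absorb algorithm: starts from a single letter shared by all
#' groups, splits letters on every significant pair, absorbs redundant
#' letters, and assigns letters deterministically (letter classes ordered by
#' the positions of their members in the supplied group ordering). Groups
#' sharing a letter are not significantly different.
#'
#' @param pairwise data.frame with columns `group1`, `group2`, `p_adj` (as
#'   returned by [tukey_hsd()]), covering every pair of `groups`
#' @param groups group names in display order; defaults to the sorted names
#'   appearing in `pairwise`
#' @param alpha significance threshold
#' @return Named character vector, group -> letter string (e.g. `"ab"`).
#' @export
compact_letters <- function(pairwise, groups = NULL, alpha = 0.05) {
  if (is.null(groups))
    groups <- sort(unique(c(pairwise$group1, pairwise$group2)))
  sig <- pairwise[!is.na(pairwise$p_adj) & pairwise$p_adj < alpha, , drop = FALSE]
  ## deterministic processing order
  i1 <- match(sig$group1, groups); i2 <- match(sig$group2, groups)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  sig <- sig[order(lo, hi), , drop = FALSE]
  classes <- list(groups)
  for (r in seq_len(nrow(sig))) {
    a <- sig$group1[r]; b <- sig$group2[r]
    new_classes <- list()
    for (cl in classes) {
      if (all(c(a, b) %in% cl)) {
        new_classes <- c(new_classes, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else new_classes <- c(new_classes, list(cl))
    }
    ## absorb: drop classes that are subsets of (or equal to) an earlier kept class
    kept <- list()
    for (cl in new_classes) {
      redundant <- any(vapply(kept, function(k) all(cl %in% k), logical(1)))
      if (!redundant) {
        kept <- Filter(function(k) !all(k %in% cl), kept)
        kept <- c(kept, list(cl))
      }
    }
    classes <- kept
  }
  classes <- Filter(length, classes)
  ## order classes lexicographically by member positions, then letter them
  keys <- lapply(classes, function(cl) sort(match(cl, groups)))
  ord <- do.call(order, as.data.frame(t(vapply(keys, function(k)
    c(k, rep(Inf, length(groups) - length(k))), numeric(length(groups))))))
  classes <- classes[ord]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(classes))
    for (gname in classes[[i]])
      out[gname] <- paste0(out[gname], letters[i])
  out
}

#' One-sample t-test of a single specimen against a group
#'
#' Tests whether a group's mean differs from a fixed value `x` contributed by
#' a single (typically fossil) specimen: `t = (mean - x) / (sd / sqrt(n))` on
#' `n - 1` degrees of freedom, two-tailed.
#'
#' @param x the single specimen's value
#' @param group_values values of the comparison group (n >= 2, non-constant)
#' @return List with `t`, `df`, `p`.
#' @export
one_sample_vs_group <- function(x, group_values) {
  if (length(group_values) < 2)
    mfs_domain_error("one-sample comparison needs group n >= 2")
  if (stats::sd(group_values) == 0)
    mfs_domain_error("degenerate one-sample comparison: zero group variance")
  ht <- stats::t.test(group_values, mu = x)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-tailed; reduces to Student's t when variances and sizes are equal.
#'
#' @param a,b numeric samples (each n >= 2; not both constant)
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    mfs_domain_error("Welch test needs n >= 2 in both samples")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    mfs_domain_error("degenerate Welch test: both samples constant")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Habit-level comparison of all functional variables
#'
#' For each functional variable (seven indices and three lever models, or a
#' supplied subset): group summaries per extant habit; one-way ANOVA across
#' habits; when significant, Tukey-Kramer post hocs summarized as compact
#' letters; one-sample t-tests of the focal fossil specimen against each
#' habit; and Welch t-tests of the non-focal fossil sample against each
#' habit. Fossils never enter the ANOVA.
#'
#' @param d a [mfs_data] dataset
#' @param variables functional variable names (default all ten)
#' @param alpha significance threshold (default 0.05)
#' @param chain_angle_deg passed to [ma_profile()]
#' @return Object of class `habit_comparison`: list of per-variable results
#'   (`group_summaries`, `anova`, `tukey`, `letters`, `fossil_one_sample`,
#'   `mesotheriid_welch`, `focal_value`) plus `alpha`. `summary()` renders a
#'   mean +/- SD table with letters and fossil significance flags.
#' @export
compare_habits <- function(d, variables = FUNCTIONAL_VARS, alpha = 0.05,
                           chain_angle_deg = 180) {
  ft <- functional_table(d, chain_angle_deg = chain_angle_deg)
  small <- names(which(table(d$group[d$group %in% HABITS]) < 3))
  if (length(small))
    warning(sprintf("small habit sample(s) (n < 3): %s",
                    paste(small, collapse = ", ")), call. = FALSE)
  res <- list()
  for (v in variables) {
    val <- ft[[v]]
    extant <- d$group %in% HABITS & !is.na(val)
    gs <- lapply(split(val[extant], d$group[extant]), function(x)
      list(mean = mean(x), sd = stats::sd(x), n = length(x)))
    gs <- gs[intersect(HABITS, names(gs))]
    av <- tukey <- NULL
    lets <- NULL
    if (sum(extant) > length(gs) && length(gs) >= 2 &&
        stats::var(val[extant]) > 0) {
      av <- one_way_anova(val[extant], d$group[extant])
      if (av$p < alpha) {
        tukey <- tukey_hsd(val[extant], d$group[extant])
        lets <- compact_letters(tukey, groups = intersect(HABITS, names(gs)),
                                alpha = alpha)
      }
    }
    focal_val <- val[d$focal][1]
    one_sample <- list()
    if (length(focal_val) && !is.na(focal_val))
      for (h in names(gs))
        if (gs[[h]]$n >= 2 && gs[[h]]$sd > 0)
          one_sample[[h]] <- one_sample_vs_group(
            focal_val, val[extant & d$group == h])
    meso <- d$group == "mesotheriid_fossil" & !d$focal & !is.na(val)
    welch <- list()
    if (sum(meso) >= 2)
      for (h in names(gs))
        if (gs[[h]]$n >= 2)
          welch[[h]] <- welch_t(val[meso], val[extant & d$group == h])
    res[[v]] <- list(variable = v, group_summaries = gs, anova = av,
                     tukey = tukey, letters = lets,
                     fossil_one_sample = one_sample,
                     mesotheriid_welch = welch,
                     focal_value = if (length(focal_val)) focal_val else NA_real_,
                     meso_mean = if (any(meso)) mean(val[meso]) else NA_real_,
                     meso_sd = if (sum(meso) >= 2) stats::sd(val[meso]) else NA_real_)
  }
  structure(list(variables = res, alpha = alpha), class = "habit_comparison")
}

#' @export
print.habit_comparison <- function(x, ...) {
  print(summary(x), ...)
  invisible(x)
}

#' @rdname compare_habits
#' @param object a `habit_comparison` object
#' @param ... unused
#' @return `summary()` returns a data.frame, one row per variable: per-habit
#'   `mean +/- sd` with compact letters (letters only when the ANOVA is
#'   significant), the fossil sample summary with the habits it differs from
#'   (Welch), and the focal value with the habits it differs from
#'   (one-sample t).
#' @export
summary.habit_comparison <- function(object, ...) {
  rows <- lapply(object$variables, function(r) {
    cells <- vapply(HABITS, function(h) {
      g <- r$group_summaries[[h]]
      if (is.null(g)) return("")
      lab <- sprintf("%.1f ± %.1f", g$mean, g$sd)
      if (!is.null(r$letters) && nzchar(r$letters[h] %||% ""))
        lab <- paste0(lab, " ", r$letters[h])
      lab
    }, "")
    sig_of <- function(tests) {
      hit <- names(tests)[vapply(tests, function(tt) tt$p < object$alpha, logical(1))]
      if (length(hit)) paste(hit, collapse = ",") else ""
    }
    meso <- if (is.na(r$meso_mean)) "" else
      sprintf("%.1f ± %.1f", r$meso_mean, r$meso_sd)
    focal <- if (is.na(r$focal_value)) "" else sprintf("%.2f", r$focal_value)
    c(variable = r$variable, cells,
      other_mesotheriids = meso, meso_differs_from = sig_of(r$mesotheriid_welch),
      focal = focal, focal_differs_from = sig_of(r$fossil_one_sample),
      anova_p = if (is.null(r$anova)) "" else format(r$anova$p, digits = 3))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Variables with significant habit effects
#'
#' @param x a `habit_comparison` object
#' @return Character vector of variable names whose ANOVA p-value is below
#'   the comparison's alpha (the variables that carry compact letters).
#' @export
significant_variables <- function(x) {
  names(Filter(function(r) !is.null(r$anova) && r$anova$p < x$alpha,
               x$variables))
}
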