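test_that("one-way ANOVA reproduces hand-computed fixtures", {
  # SSB = 16, SSW = 1.5 -> F = (16/2) / (1.5/3) = 16 on (2, 3) df
  a <- one_way_anova(c(0, 1, 2, 3, 4, 5), rep(c("g1", "g2", "g3"), each = 2))
  expect_equal(a$F, 16)
  expect_equal(c(a$df_between, a$df_within), c(2, 3))
  expect_equal(a$p, 1 - pf(16, 2, 3), tolerance = 1e-12)

  # identical groups: no effect
  a0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  expect_error(one_way_anova(rep(5, 6), rep(c("x", "y"), each = 3)),
               class = "mfs_domain_error")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(21)
  x <- rnorm(8); y <- rnorm(9, 1)
  a <- one_way_anova(c(x, y), rep(c("x", "y"), c(8, 9)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
})

test_that("Tukey-Kramer post hocs behave at the extremes and match the t identity", {
  # near-identical groups: adjusted p ~ 1
  set.seed(23)
  v <- rnorm(12)
  tk0 <- tukey_hsd(c(v, v), rep(c("a", "b"), each = 12))
  expect_gt(tk0$p_adj, 0.999)

  # huge separation: everything significant
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1), rnorm(5, 20, 0.1))
  tk1 <- tukey_hsd(v, rep(c("a", "b", "c"), each = 5))
  expect_true(all(tk1$p_adj < 1e-6))

  # equal-n two-group case: Tukey p equals the pooled two-sample t p
  # (studentized range q = sqrt(2) * |t|)
  x <- rnorm(6); y <- rnorm(6, 0.8)
  tk2 <- tukey_hsd(c(x, y), rep(c("a", "b"), each = 6))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(ptukey(sqrt(2) * abs(tt$statistic), 2, 10, lower.tail = FALSE),
               tk2$p_adj, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("compact letters cover the canonical patterns", {
  pw <- function(g1, g2, p) data.frame(group1 = g1, group2 = g2, p_adj = p,
                                       stringsAsFactors = FALSE)
  gs <- c("a1", "a2", "a3")
  allpairs <- pw(c("a1", "a1", "a2"), c("a2", "a3", "a3"), c(1, 1, 1))
  expect_equal(unname(compact_letters(allpairs, gs)), c("a", "a", "a"))

  allsig <- pw(c("a1", "a1", "a2"), c("a2", "a3", "a3"), c(0.001, 0.001, 0.001))
  expect_equal(unname(compact_letters(allsig, gs)), c("a", "b", "c"))
})

test_that("compact letters reproduce the epicondylar-index significance pattern", {
  # significant pairs: D-T, D-F, T-S, T-F, C-F, S-F; everything else ns
  habits <- c("digger", "terrestrial", "climber", "swimmer", "flyer")
  pairs <- t(combn(habits, 2))
  sig <- c("digger|terrestrial", "digger|flyer", "terrestrial|swimmer",
           "terrestrial|flyer", "climber|flyer", "swimmer|flyer")
  p <- ifelse(paste(pairs[, 1], pairs[, 2], sep = "|") %in% sig, 0.01, 0.5)
  lets <- compact_letters(data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                                     p_adj = p, stringsAsFactors = FALSE),
                          groups = habits)
  expect_equal(lets, c(digger = "a", terrestrial = "b", climber = "ab",
                       swimmer = "a", flyer = "c"))
})

test_that("compact letters are logically equivalent to the pairwise pattern", {
  # property: share a letter <=> pair not significant; audited exhaustively
  # over random significance patterns
  set.seed(29)
  habits <- c("g1", "g2", "g3", "g4", "g5")
  pairs <- t(combn(habits, 2))
  for (rep in 1:25) {
    p <- ifelse(runif(nrow(pairs)) < 0.4, 0.01, 0.5)
    # reject patterns violating transitivity is unnecessary: the display must
    # simply match the pattern pair-by-pair
    lets <- compact_letters(data.frame(group1 = pairs[, 1],
                                       group2 = pairs[, 2], p_adj = p,
                                       stringsAsFactors = FALSE),
                            groups = habits)
    for (k in seq_len(nrow(pairs))) {
      shared <- length(intersect(strsplit(lets[pairs[k, 1]], "")[[1]],
                                 strsplit(lets[pairs[k, 2]], "")[[1]])) > 0
      expect_equal(shared, p[k] >= 0.05,
                   label = sprintf("pair %s-%s rep %d", pairs[k, 1], pairs[k, 2], rep))
    }
  }
})

test_that("compact letters agree with the multcomp reference on fitted data", {
  skip_if_not_installed("multcomp")
  set.seed(31)
  g <- factor(rep(c("c1", "c2", "c3", "c4"), times = c(6, 7, 5, 8)))
  y <- rnorm(length(g), mean = c(c1 = 0, c2 = 0.4, c3 = 3, c4 = 3.2)[g])
  tk <- tukey_hsd(y, g)
  mine <- compact_letters(tk, groups = levels(g))
  fit <- stats::aov(y ~ g)
  ref <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")))
  # same sharing structure (letter names may differ)
  share <- function(lets, a, b)
    length(intersect(strsplit(lets[[a]], "")[[1]],
                     strsplit(lets[[b]], "")[[1]])) > 0
  for (pair in combn(levels(g), 2, simplify = FALSE))
    expect_equal(share(mine, pair[1], pair[2]),
                 share(ref$mcletters$Letters, pair[1], pair[2]))
})

test_that("one-sample and Welch tests match hand computations", {
  o <- one_sample_vs_group(0, c(1, 2, 3))
  expect_equal(o$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(o$df, 2)
  expect_equal(o$p, 0.0742, tolerance = 1e-3)
  expect_equal(one_sample_vs_group(2, c(1, 2, 3))$t, 0)
  expect_equal(one_sample_vs_group(2, c(1, 2, 3))$p, 1)
  expect_error(one_sample_vs_group(1, c(2, 2)), class = "mfs_domain_error")

  w <- welch_t(c(0, 1), c(10, 11))
  expect_equal(w$t, -14.1421, tolerance = 1e-4)
  expect_equal(w$df, 2, tolerance = 1e-9)
  expect_equal(w$p, 0.00496, tolerance = 1e-3)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)

  # Welch reduces to Student's t for equal variances and sizes
  set.seed(37)
  x <- rnorm(10); y <- 2 + (x - mean(x)) * 1  # same spread
  ws <- welch_t(x, y + rnorm(10, 0, 1e-12))
  st <- t.test(x, y, var.equal = TRUE)
  expect_equal(ws$df, 18, tolerance = 1e-6)
  expect_equal(ws$t, unname(st$statistic), tolerance = 1e-6)
})

test_that("tests are invariant to unit rescaling", {
  set.seed(41)
  v <- rnorm(15); g <- rep(c("a", "b", "c"), each = 5)
  a1 <- one_way_anova(v, g); a2 <- one_way_anova(v * 100, g)
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
  w1 <- welch_t(v[1:5], v[6:10]); w2 <- welch_t(v[1:5] * 100, v[6:10] * 100)
  expect_equal(w1$p, w2$p, tolerance = 1e-9)
})

test_that("compare_habits assembles the full comparison on a study-like table", {
  d <- study_data()
  expect_warning(hc <- compare_habits(d), "small habit sample")
  expect_equal(length(hc$variables), 10)
  ei <- hc$variables$EI
  expect_equal(vapply(ei$group_summaries, `[[`, 0L, "n"),
               c(digger = 4L, terrestrial = 15L, climber = 9L,
                 swimmer = 8L, flyer = 2L))
  expect_equal(ei$anova$df_between, 4)
  expect_equal(ei$anova$df_within, 38 - 5)
  # fossils never enter the ANOVA; they appear via the t-test channels
  expect_true(length(ei$fossil_one_sample) >= 1)
  expect_true(length(ei$mesotheriid_welch) >= 1)
  # letters only where the ANOVA is significant
  for (r in hc$variables) {
    if (is.null(r$anova) || r$anova$p >= hc$alpha) expect_null(r$letters)
    else expect_true(all(nzchar(r$letters)))
  }
  s <- summary(hc)
  expect_equal(nrow(s), 10)
  expect_true(all(c("digger", "other_mesotheriids", "focal") %in% names(s)))
})

test_that("a single shifted variable is the only one gaining letters", {
  mk <- function(habit, oi) habit_params(
    habit, n = 8, hl_log_mean = 1, hl_log_sd = 0.05,
    index_means = setNames(c(10, 25, oi, 90, 105, 10, 8, 5, 18),
                           mfspace:::FREE_INDEX_VARS),
    index_sds = setNames(c(0.5, 0.5, 0.8, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                         mfspace:::FREE_INDEX_VARS))
  params <- list(digger = mk("digger", 40), terrestrial = mk("terrestrial", 10),
                 climber = mk("climber", 10))
  d <- make_study_like_dataset(params, seed = 3, include_holotype = FALSE)
  # a strict threshold separates the constructed effect from sampling noise
  hc <- compare_habits(d, alpha = 1e-3)
  sig <- significant_variables(hc)
  # OI is shifted by construction; MAe inherits the shift through the lever
  # chain (it is a monotone function of OI); every other variable is null
  expect_setequal(sig, c("OI", "MAe"))

  # single-habit dataset: no letters anywhere
  d1 <- make_study_like_dataset(params["digger"], seed = 4,
                                include_holotype = FALSE)
  hc1 <- compare_habits(d1)
  expect_equal(length(significant_variables(hc1)), 0)
})
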