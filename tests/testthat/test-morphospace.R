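# Brute-force eigendecomposition oracle for PCA, independent of prcomp()
eigen_pca_oracle <- function(x) {
  xc <- sweep(x, 2, colMeans(x), "-")
  e <- eigen(stats::cov(xc), symmetric = TRUE)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  list(scores = xc %*% load, loadings = load,
       variance_explained = 100 * e$values / sum(e$values))
}

test_that("PCA matches an independent eigendecomposition oracle", {
  set.seed(101)
  for (rep in 1:5) {
    x <- matrix(rnorm(18), 6, 3)
    p <- pca_fit(x)
    o <- eigen_pca_oracle(x)
    expect_equal(unname(p$loadings), o$loadings, tolerance = 1e-8)
    expect_equal(unname(p$scores), o$scores, tolerance = 1e-8)
    expect_equal(p$variance_explained, o$variance_explained, tolerance = 1e-8)
  }
})

test_that("PCA satisfies reconstruction, orthogonality and sign conventions", {
  set.seed(103)
  x <- matrix(rnorm(60), 12, 5)
  p <- pca_fit(x)
  xc <- sweep(x, 2, p$center, "-")
  expect_equal(p$scores %*% t(p$loadings), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(t(p$loadings) %*% p$loadings, diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p$variance_explained) <= 1e-10))
  expect_equal(sum(p$variance_explained), 100, tolerance = 1e-10)
  expect_equal(unname(colMeans(p$scores)), rep(0, 5), tolerance = 1e-12)
  for (j in 1:5) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # score columns uncorrelated
  cc <- stats::cov(p$scores)
  expect_equal(cc[lower.tri(cc)], rep(0, 10), tolerance = 1e-8)
})

test_that("two perfectly correlated columns put all variance on PC1", {
  x <- cbind(a = c(-1.2608, -0.3571, 0.2237, 1.3942),
             b = c(-1.2608, -0.3571, 0.2237, 1.3942))
  p <- pca_fit(zscore(x))
  expect_equal(p$variance_explained, c(100, 0), tolerance = 1e-8)
  expect_error(pca_fit(matrix(c(1, NA, 2, 3), 2)), class = "mfs_validation_error")
})

test_that("convex hulls are counterclockwise, minimal, and contain their group", {
  tri <- matrix(c(0, 0, 2, 0, 1, 2), ncol = 2, byrow = TRUE)
  h <- habit_hulls(tri, rep("digger", 3))
  expect_equal(nrow(h$digger), 3)
  v <- h$digger; j <- c(2, 3, 1)
  expect_gt(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]), 0)  # CCW signed area

  # unit square corners + center: hull is the 4 corners (brute-force checkable)
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 0.5, 0.5), ncol = 2, byrow = TRUE)
  h2 <- habit_hulls(sq, rep("climber", 5))
  expect_equal(nrow(h2$climber), 4)
  expect_true(all(apply(sq[1:4, ], 1, function(p)
    any(abs(h2$climber[, 1] - p[1]) + abs(h2$climber[, 2] - p[2]) < 1e-12))))

  # 2-specimen habit: degenerate segment hull; fossils get no hull
  seg <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  h3 <- habit_hulls(seg, c("flyer", "flyer", "mesotheriid_fossil"))
  expect_equal(nrow(h3$flyer), 2)
  expect_null(h3$mesotheriid_fossil)
})

test_that("every specimen lies inside or on its habit's hull", {
  fit <- mfs(study_data(), block = "functional")
  for (h in names(fit$hulls)) {
    pts <- fit$scores[fit$group == h, 1:2, drop = FALSE]
    hull <- fit$hulls[[h]]
    if (nrow(hull) < 3) next
    for (i in seq_len(nrow(pts)))
      expect_true(point_in_hull(pts[i, ], hull))
  }
})

test_that("the two morphospace blocks fit, project, and expose residuals", {
  d <- study_data()
  fo <- mfs(d, block = "osteological")
  ff <- mfs(d, block = "functional")
  expect_equal(ncol(fo$loadings), 9)
  expect_equal(ncol(ff$loadings), 10)
  expect_equal(fo$cumulative_variance,
               sum(fo$variance_explained[1:2]), tolerance = 1e-12)
  expect_true(all(c("digger", "terrestrial", "climber", "swimmer", "flyer")
                  %in% names(ff$hulls)))
  expect_equal(nrow(ff$hulls$flyer), 2)  # n = 2 habit: segment hull

  # projecting the training data reproduces the training scores
  expect_equal(unname(predict(fo, d)), unname(fo$scores), tolerance = 1e-8)
  expect_equal(unname(predict(ff, d)), unname(ff$scores), tolerance = 1e-8)

  # residuals only defined where a size correction happened
  expect_equal(dim(residuals(fo)), c(nrow(d), 9))
  expect_error(residuals(ff), class = "mfs_domain_error")

  # identical specimens are degenerate
  same <- as.data.frame(d)[rep(1, 4), ]
  same$specimen_id <- paste0("s", 1:4)
  expect_error(mfs(mfs_data(same), block = "functional"),
               class = "mfs_degenerate_column_error")
})

test_that("habit structure in the generator shows up as clustering, and label permutation destroys it", {
  # well-separated generator parameters with tight spreads
  mk <- function(habit, mu) habit_params(
    habit, n = 8, hl_log_mean = 1, hl_log_sd = 0.1,
    index_means = setNames(mu, mfspace:::FREE_INDEX_VARS),
    index_sds = setNames(rep(0.4, 9), mfspace:::FREE_INDEX_VARS))
  params <- list(
    digger      = mk("digger",      c(20, 45, 30, 70, 110, 18, 16, 25, 30)),
    terrestrial = mk("terrestrial", c(8, 20, 15, 95, 100, 8, 6, 10, 15)),
    climber     = mk("climber",     c(13, 30, 8, 120, 130, 5, 10, 5, 22)))
  d <- make_study_like_dataset(params, seed = 9, include_holotype = FALSE)
  fit <- mfs(d, block = "functional")
  sc <- fit$scores[, 1:2]
  extant <- fit$group %in% mfspace:::HABITS
  centroid_gap <- function(groups) {
    cent <- lapply(split(seq_len(nrow(sc))[extant], groups[extant]),
                   function(i) colMeans(sc[i, , drop = FALSE]))
    own <- other <- 0
    for (i in which(extant)) {
      dists <- vapply(cent, function(cc) sum((sc[i, ] - cc)^2), 0)
      own <- own + dists[[groups[i]]]
      other <- other + min(dists[names(dists) != groups[i]])
    }
    other - own  # positive when specimens sit nearer their own centroid
  }
  observed <- centroid_gap(fit$group)
  expect_gt(observed, 0)
  set.seed(5)
  perm <- fit$group
  perm[extant] <- sample(perm[extant])
  expect_lt(centroid_gap(perm), observed)
})
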