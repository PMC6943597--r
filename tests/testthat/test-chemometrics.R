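test_that("autoscaling yields unit-variance columns and flags constants", {
  m <- cbind(a = c(1, 2, 3, 4), b = rep(7, 4), c = c(0, 0, 5, 10))
  v <- as_volatiles(m, sprintf("g%d", 1:4), rep(c("LSM", "SW"), 2))
  s <- scale_volatiles(v, "autoscale")
  expect_equal(unname(colMeans(s$values)), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(s$values[, c("a", "c")], 2, var)), c(1, 1))
  expect_true(s$zero_variance[["b"]])
  expect_equal(unname(s$values[, "b"]), rep(0, 4))
  expect_equal(unname(s$scale[["b"]]), 1)
})

test_that("a stored transform reproduces the training rows", {
  v <- random_volatiles(n = 9, p = 6, seed = 2)
  for (mode in c("autoscale", "pareto", "center")) {
    s <- scale_volatiles(v, mode)
    expect_equal(apply_scaling(s, v), s$values)
  }
})

test_that("PCA of a rank-1 matrix explains everything in one component", {
  base <- c(1, 2, 3, 4, 5)
  m <- outer(c(1, 2, 3, 4), base)
  colnames(m) <- sprintf("C%02d", 1:5)
  v <- as_volatiles(m, sprintf("g%d", 1:4), rep(c("LSM", "SW"), 2))
  fit <- fit_pca(v, n_components = 1, scaling = "center")
  expect_equal(fit$explained_variance_ratio[1], 1)
})

test_that("full-rank PCA reconstructs the scaled matrix and is orthonormal", {
  v <- random_volatiles(n = 10, p = 6, seed = 4, zero_frac = 0)
  s <- scale_volatiles(v)
  fit <- fit_pca(s, n_components = 6)
  gram <- crossprod(fit$loadings)
  expect_equal(gram, diag(6), tolerance = 1e-8, ignore_attr = TRUE)
  recon <- fit$scores %*% t(fit$loadings)
  expect_equal(recon, s$values, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(fit$explained_variance_ratio), 1 + 1e-12)
})

test_that("PCA matches an eigendecomposition of the covariance matrix", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rexp(80, 0.1), nrow = 10)
    colnames(m) <- sprintf("C%02d", 1:8)
    v <- as_volatiles(m, sprintf("g%d", 1:10),
                      rep(c("LSM", "SW"), 5))
    fit <- fit_pca(v, n_components = 3)
    s <- scale_volatiles(v)
    eig <- eigen(stats::cov(s$values), symmetric = TRUE)
    # ratios use the n-1 denominator consistently, so they agree
    expect_equal(fit$explained_variance_ratio,
                 (eig$values / sum(eig$values))[1:3], tolerance = 1e-8)
    for (a in 1:3) {
      cosine <- abs(sum(fit$loadings[, a] * eig$vectors[, a]))
      expect_gt(cosine, 1 - 1e-8)
      expect_equal(unname(fit$scores[, a]),
                   as.numeric(s$values %*% fit$loadings[, a]))
    }
  }
})

test_that("explained-variance ratios ignore the order of germplasm rows", {
  v <- random_volatiles(n = 11, p = 7, seed = 6)
  fit <- fit_pca(v, 3)
  set.seed(1)
  perm <- v[sample(nrow(v)), ]
  fit_p <- fit_pca(perm, 3)
  expect_equal(fit$explained_variance_ratio,
               fit_p$explained_variance_ratio, tolerance = 1e-10)
})

test_that("components beyond the matrix rank are truncated with a warning", {
  m <- outer(c(1, 2, 3, 4, 5), c(2, 1, 3, 0.5))
  colnames(m) <- sprintf("C%02d", 1:4)
  v <- as_volatiles(m, sprintf("g%d", 1:5),
                    rep(c("LSM", "SW", "P"), length.out = 5))
  expect_warning(fit <- fit_pca(v, 3, scaling = "center"),
                 "truncating")
  expect_equal(ncol(fit$scores), 1)
})

test_that("first NIPALS weight is the top left singular vector of X'Y", {
  for (seed in 1:6) {
    d <- random_xy(n = 15, p = 9, groups = sample(2:3, 1), seed = seed)
    fit <- nipals_pls(d$x, d$y, n_components = 1)
    sv <- svd(crossprod(d$x, d$y))
    cosine <- abs(sum(fit$W[, 1] * sv$u[, 1]))
    expect_gt(cosine, 1 - 1e-8)
  }
})

test_that("scores are orthogonal and weights unit norm in fitted models", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- random_volatiles(n = 14, p = 10, seed = seed,
                          species = sample(c("LSM", "SW", "P"), 14,
                                           replace = TRUE))
    fit <- fit_plsda(v, n_components = 3)
    expect_equal(unname(sqrt(colSums(fit$W^2))),
                 rep(1, fit$n_components), tolerance = 1e-10)
    tt <- crossprod(fit$T)
    off <- tt - diag(diag(tt))
    norms <- sqrt(diag(tt))
    expect_true(all(abs(off) < 1e-8 * outer(norms, norms)))
    expect_true(all(fit$ssy >= 0))
  }
})

test_that("duplicating every germplasm leaves the weights unchanged", {
  v <- random_volatiles(n = 10, p = 6, seed = 8)
  fit1 <- fit_plsda(v, n_components = 2)
  v2 <- v
  v2$germplasm <- paste0(v$germplasm, "_dup")
  doubled <- dplyr::bind_rows(v, v2)
  fit2 <- fit_plsda(doubled, n_components = 2)
  expect_equal(fit2$W, fit1$W, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("permuted labels explain little response variance", {
  set.seed(99)
  v <- random_volatiles(n = 24, p = 12, seed = 99,
                        species = rep(c("LSM", "SW"), each = 12))
  shuffled <- sample(v$species)
  fit <- fit_plsda(v, groups = shuffled, n_components = 2)
  observed_r2 <- sum(fit$ssy) / fit$ssy_total
  # permutation reference for the same statistic
  ref <- replicate(200, {
    f <- fit_plsda(v, groups = sample(shuffled), n_components = 2)
    sum(f$ssy) / f$ssy_total
  })
  expect_gt(mean(ref >= observed_r2), 0.05)
})

test_that("VIP is exactly 1 for a single compound and obeys the identity", {
  one <- as_volatiles(matrix(c(1, 5, 2, 8), ncol = 1,
                             dimnames = list(NULL, "only")),
                      sprintf("g%d", 1:4), rep(c("LSM", "SW"), 2))
  fit <- fit_plsda(one, n_components = 1)
  expect_equal(vip_scores(fit)$vip, 1)

  for (seed in 1:6) {
    set.seed(seed)
    p <- sample(5:30, 1)
    v <- random_volatiles(n = 16, p = p, seed = seed,
                          species = sample(c("LSM", "SW", "P"), 16,
                                           replace = TRUE))
    fit <- fit_plsda(v, n_components = sample(1:3, 1))
    vip <- vip_scores(fit)$vip
    expect_equal(sum(vip^2), p, tolerance = 1e-8)
    expect_true(all(vip >= 0))
  }
})

test_that("one-component VIP reduces to sqrt(p) * |w|", {
  v <- random_volatiles(n = 12, p = 7, seed = 13)
  fit <- fit_plsda(v, n_components = 1)
  expect_equal(vip_scores(fit)$vip,
               sqrt(7) * abs(unname(fit$W[, 1])), tolerance = 1e-10)
})

test_that("a strongly planted marker attains the maximum VIP", {
  for (seed in 1:20) {
    sim <- simulate_volatiles(n_per_species = c(LSM = 15, SW = 15),
                              n_compounds = 20,
                              n_markers_per_species = 1,
                              log_effect = 4, wild_fraction = 0,
                              seed = seed)
    fit <- fit_plsda(sim$profiles, n_components = 2)
    vip <- vip_scores(fit)
    top <- vip$compound[which.max(vip$vip)]
    expect_true(top %in% sim$truth$compound)
  }
})

test_that("first-component direction agrees with an independent PLS-DA", {
  skip_if_not_installed("mixOmics")
  v <- random_volatiles(n = 14, p = 8, seed = 17,
                        species = rep(c("LSM", "SW"), 7))
  fit <- fit_plsda(v, n_components = 2)
  ref <- mixOmics::plsda(compound_matrix(v), factor(v$species), ncomp = 2)
  w_ref <- ref$loadings$X[, 1]
  cosine <- abs(sum(fit$W[, 1] * w_ref) /
                  sqrt(sum(fit$W[, 1]^2) * sum(w_ref^2)))
  expect_gt(cosine, 1 - 1e-6)
})
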