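test_that("degenerate and maximally separated inputs are handled", {
  res <- group_difference_test(rep(3, 8), rep(c("a", "b"), each = 4),
                               positive = "a")
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")

  # disjoint supports: all positives above all negatives
  res <- group_difference_test(c(10, 11, 12, 13, 14, 1, 2, 3, 4, 5),
                               rep(c("a", "b"), each = 5),
                               positive = "a")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$direction, "higher-in-positive")

  expect_error(group_difference_test(1:3, c("a", "a", "b")),
               "at least 2 values")
})

test_that("the Wilcoxon branch matches exact rank-sum enumeration", {
  # heavy-tailed values with an extreme outlier force the rank branch
  for (seed in 1:5) {
    set.seed(seed)
    n1 <- sample(4:6, 1)
    n2 <- sample(4:6, 1)
    x <- c(exp(rnorm(n1 - 1, 0, 2)), 1e6)
    y <- exp(rnorm(n2, 1, 2))
    res <- group_difference_test(c(x, y), rep(c("a", "b"), c(n1, n2)),
                                 positive = "a")
    expect_equal(res$method, "wilcoxon")
    # oracle: enumerate all assignments of ranks to the positive group
    ranks <- rank(c(x, y))
    w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(n1 + n2, n1)
    w_all <- apply(combos, 2, function(idx) {
      sum(rank(c(x, y))[idx]) - n1 * (n1 + 1) / 2
    })
    p_exact <- min(1, 2 * min(mean(w_all <= w_obs),
                              mean(w_all >= w_obs)))
    expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  }
})

test_that("null rejection rate of the gated test is near alpha", {
  set.seed(7)
  p <- replicate(300, {
    vals <- exp(rnorm(24, log(50), 1))
    g <- sample(rep(c("a", "b"), 12))
    group_difference_test(vals, g, positive = "a")$p_value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 300))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("standard contrasts reproduce the panel geometry", {
  sim <- simulate_volatiles(n_per_species = c(LSM = 29, SW = 24, P = 8,
                                              Lem = 5, CCL = 16),
                            wild_fraction = 0.2, seed = 1)
  cs <- standard_contrasts(sim$profiles)
  lsm <- cs[cs$contrast == "LSM_vs_rest", ]
  expect_equal(length(lsm$positive[[1]]), 29)
  # rest excludes the 16 clementines: 24 + 8 + 5
  expect_equal(length(lsm$negative[[1]]), 37)
  ccl <- cs[cs$contrast == "CCL_vs_LSM_SW", ]
  expect_equal(length(ccl$positive[[1]]), 16)
  expect_equal(length(ccl$negative[[1]]), 53)
  for (i in seq_len(nrow(cs))) {
    expect_length(intersect(cs$positive[[i]], cs$negative[[i]]), 0)
  }

  no_wild <- simulate_volatiles(n_per_species = c(LSM = 10, SW = 10),
                                wild_fraction = 0, seed = 2)
  expect_warning(cs2 <- standard_contrasts(no_wild$profiles),
                 "wild_vs_cultivar")
  expect_false("wild_vs_cultivar" %in% cs2$contrast)
})

test_that("planted markers are recovered with matching directions", {
  for (seed in 1:20) {
    sim <- simulate_volatiles(n_per_species = c(LSM = 20, SW = 20),
                              n_compounds = 60,
                              n_markers_per_species = 3,
                              log_effect = 4, base_log_sd = 0.5,
                              marker_direction = "mixed",
                              wild_fraction = 0, seed = seed)
    cs <- suppressWarnings(standard_contrasts(sim$profiles))
    row <- cs[cs$contrast == "LSM_vs_rest", ]
    ms <- select_markers(sim$profiles, contrast_row = row)
    planted <- sim$truth[sim$truth$species == "LSM", ]
    idx <- match(planted$compound, ms$compound)
    expect_false(any(is.na(idx)))
    expect_equal(ms$direction[idx],
                 ifelse(planted$direction == "up",
                        "higher-in-positive", "lower-in-positive"))
  }
})

test_that("marker selection ignores row and column order", {
  sim <- simulate_volatiles(n_per_species = c(LSM = 15, SW = 15),
                            n_compounds = 25, wild_fraction = 0,
                            seed = 42)
  cs <- suppressWarnings(standard_contrasts(sim$profiles))
  row <- cs[cs$contrast == "LSM_vs_rest", ]
  ms <- select_markers(sim$profiles, contrast_row = row)
  set.seed(1)
  shuffled <- sim$profiles[sample(nrow(sim$profiles)),
                           c("germplasm", "species", "origin",
                             sample(compound_names(sim$profiles)))]
  ms2 <- select_markers(shuffled, contrast_row = row)
  expect_equal(ms2$compound, ms$compound)
  expect_equal(ms2$vip, ms$vip, tolerance = 1e-8)
  expect_equal(ms2$p_value, ms$p_value, tolerance = 1e-8)
})

test_that("tightening either threshold never enlarges the marker set", {
  sim <- simulate_volatiles(n_per_species = c(LSM = 15, SW = 15),
                            n_compounds = 25, wild_fraction = 0,
                            seed = 8)
  cs <- suppressWarnings(standard_contrasts(sim$profiles))
  row <- cs[cs$contrast == "LSM_vs_rest", ]
  loose <- select_markers(sim$profiles, contrast_row = row,
                          vip_threshold = 1, p_threshold = 0.1)
  tight_vip <- select_markers(sim$profiles, contrast_row = row,
                              vip_threshold = 1.5, p_threshold = 0.1)
  tight_p <- select_markers(sim$profiles, contrast_row = row,
                            vip_threshold = 1, p_threshold = 0.01)
  expect_true(all(tight_vip$compound %in% loose$compound))
  expect_true(all(tight_p$compound %in% loose$compound))
  expect_lte(nrow(tight_vip), nrow(loose))
  expect_lte(nrow(tight_p), nrow(loose))

  empty <- select_markers(sim$profiles, contrast_row = row,
                          vip_threshold = Inf)
  expect_equal(nrow(empty), 0)
})

test_that("marker sets come out sorted by VIP with both gates satisfied", {
  sim <- simulate_volatiles(n_per_species = c(LSM = 15, SW = 15),
                            n_compounds = 25, wild_fraction = 0,
                            seed = 15)
  cs <- suppressWarnings(standard_contrasts(sim$profiles))
  ms <- select_markers(sim$profiles, contrast_row = cs[1, ])
  expect_true(all(diff(ms$vip) <= 0))
  expect_true(all(ms$vip > 1.5))
  expect_true(all(ms$p_value < 0.05))
})
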