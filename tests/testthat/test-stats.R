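test_that("BH adjustment matches the hand-worked and brute-force oracles", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 6)), rep(1, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  with_seed(41, {
    for (i in 1:200) {
      p <- runif(sample(1:12, 1))
      expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
    }
  })
})

test_that("exact sign-flip enumeration reproduces the brute-force threshold", {
  with_seed(42, {
    for (i in 1:5) {
      D <- matrix(rnorm(5 * 30), 5, 30)
      pr <- permutation_max_t(D, n_perm = 500, seed = i)
      expect_true(pr$exact)
      expect_identical(pr$n_perm, 32L)
      expect_equal(pr$threshold, perm_thr_brute(D), tolerance = 1e-12)
    }
  })
})

test_that("max-statistic FWER is near nominal and power is retained", {
  # null: family-wise error across 200 simulations
  hits <- vapply(1:200, function(i) {
    D <- with_seed(5000 + i, array(rnorm(10 * 50 * 4), c(10, 50, 4)))
    any(permutation_max_t(D, n_perm = 300, seed = i)$significant)
  }, TRUE)
  ci <- 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(hits) - 0.05), ci + 0.01)

  # a constant large effect at voxel 1 is detected; null voxels stay controlled
  det <- vapply(1:50, function(i) {
    D <- with_seed(6000 + i, cbind(2 + rnorm(10, sd = 0.5),
                                   matrix(rnorm(10 * 99), 10)))
    pr <- permutation_max_t(D, n_perm = 300, seed = i)
    pr$significant[1]
  }, TRUE)
  expect_gte(mean(det), 0.99)
  expect_error(permutation_max_t(matrix(rnorm(40), 4), n_perm = 50), ">= 100")
})

test_that("permutation results are invariant to subject ordering", {
  # exact-enumeration path: the whole result is order-invariant
  D5 <- with_seed(43, matrix(rnorm(5 * 60), 5, 60))
  pr1 <- permutation_max_t(D5, n_perm = 200, seed = 9)
  pr2 <- permutation_max_t(D5[c(3, 1, 5, 2, 4), ], n_perm = 200, seed = 9)
  expect_equal(pr1$observed_t, pr2$observed_t, tolerance = 1e-12)
  expect_equal(pr1$threshold, pr2$threshold, tolerance = 1e-12)
  # sampled path: the observed statistic is order-invariant
  D <- with_seed(44, matrix(rnorm(12 * 60), 12, 60))
  pr3 <- permutation_max_t(D, n_perm = 200, seed = 9)
  pr4 <- permutation_max_t(D[sample(12), ], n_perm = 200, seed = 9)
  expect_equal(pr3$observed_t, pr4$observed_t, tolerance = 1e-12)
})

test_that("Wilcoxon handles zeros by Pratt and degenerates to p = 1", {
  w <- wilcoxon_signed_rank(c(5, 6, 7), c(5, 6, 7))
  expect_identical(w$p_value, 1)
  expect_true(w$degenerate)

  # no zeros or ties, small n: agrees with the exact signed-rank test
  x <- c(10, 12, 9, 14, 8, 11); y <- c(8, 9, 10, 10, 3, 17)
  w2 <- wilcoxon_signed_rank(x, y)
  expect_equal(w2$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)

  # with zeros: Pratt keeps them in the ranking; p stays in (0, 1)
  w3 <- wilcoxon_signed_rank(c(5, 6, 7, 9, 12, 15), c(5, 6, 7, 4, 4, 4))
  expect_false(w3$degenerate)
  expect_true(w3$p_value > 0 && w3$p_value < 1)
})

test_that("the clinical battery detects a planted NMT-only improvement", {
  hits <- vapply(1:60, function(i) {
    tab <- simulate_clinical(15, effects = list(FGA = c(NMT = 9, nonNMT = 0)),
                             seed = 3000 + i)
    rep <- clinical_battery(tab)
    q <- rep$tests$q[rep$tests$measure == "FGA" &
                       rep$tests$test == "mannwhitney_between"]
    q < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("swapping group labels flips direction but not the p-value", {
  tab <- simulate_clinical(12, effects = list(TUG = c(NMT = -5, nonNMT = 0)),
                           seed = 77)
  rep1 <- clinical_battery(tab)
  swapped <- as.data.frame(tab)
  swapped$group <- ifelse(swapped$group == "NMT", "nonNMT", "NMT")
  rep2 <- clinical_battery(clinical_table(swapped))
  b1 <- rep1$tests[rep1$tests$test == "mannwhitney_between", ]
  b2 <- rep2$tests[rep2$tests$test == "mannwhitney_between", ]
  expect_equal(b1$p, b2$p, tolerance = 1e-12)
  expect_equal(b1$direction[b1$measure == "TUG"],
               -b2$direction[b2$measure == "TUG"])
  # q >= p and KS normality reported per measure
  expect_true(all(rep1$tests$q >= rep1$tests$p - 1e-12))
  expect_identical(nrow(rep1$normality), 7L)
})

test_that("unpaired subjects are dropped with a warning; tiny groups error", {
  tab <- as.data.frame(simulate_clinical(5, seed = 2))
  tab <- tab[!(tab$subject_id == "N01" & tab$timepoint == "TPOST"), ]
  w <- capture_warnings(clinical_battery(clinical_table(tab)))
  expect_true(all(grepl("unpaired", w)) && length(w) >= 1)
  tab2 <- as.data.frame(simulate_clinical(2, seed = 3))
  tab2 <- tab2[!(tab2$subject_id == "N01" & tab2$timepoint == "TPOST"), ]
  expect_error(suppressWarnings(clinical_battery(clinical_table(tab2))),
               "< 2 paired subjects")
})

test_that("multiple correlation equals sqrt R^2 of the OLS fit", {
  with_seed(44, {
    Z <- matrix(rnorm(30 * 3), 30, 3)
    y <- Z %*% c(1, -2, 0.5) + rnorm(30)
    mc <- multiple_correlation(y, Z)
    expect_equal(mc$R, sqrt(summary(lm(y ~ Z))$r.squared), tolerance = 1e-12)
    expect_true(mc$R >= 0 && mc$R <= 1)
  })
})
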