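test_that("pearson matches hand-computed values and handles degeneracy", {
  p <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(p[["r"]], 0.8)
  expect_equal(pearson(1:10, 1:10)[["r"]], 1)
  expect_equal(pearson(1:10, -(1:10))[["r"]], -1)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  # pairwise-complete deletion
  x <- c(1, 2, NA, 4, 5); y <- c(2, 4, 9, 8, 10)
  expect_equal(pearson(x, y)[["n"]], 4)
  expect_equal(pearson(x, y)[["r"]], 1)
})

test_that("distance correlation matches a brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- if (i %% 3 == 0) x^2 else rnorm(n)
    expect_equal(distance_correlation(x, y), dcor_bruteforce(x, y),
                 tolerance = 1e-10)
  }
  # identity, affine invariance, symmetry, nonlinear dependence
  x <- c(1, 2, 3, 4, 5)
  expect_equal(distance_correlation(x, x), 1)
  expect_equal(distance_correlation(x, 3 * x + 2), 1)
  expect_equal(distance_correlation(x, x^2), dcor_bruteforce(x, x^2),
               tolerance = 1e-12)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(distance_correlation(a, b), distance_correlation(b, a))
  expect_equal(distance_correlation(2 * a - 5, b), distance_correlation(a, b),
               tolerance = 1e-12)
})

test_that("permutation p-values are seeded, bounded and null-calibrated", {
  x <- rnorm(30)
  r1 <- dcc_permutation_p(x, x, n_perm = 200, seed = 7)
  expect_equal(r1[["p"]], 1 / 201)  # no permutation beats identity
  r2 <- dcc_permutation_p(x, x, n_perm = 200, seed = 7)
  expect_identical(r1, r2)
  # under independence p is roughly uniform: check mean and spread at small n
  set.seed(3)
  ps <- replicate(60, {
    dcc_permutation_p(rnorm(20), rnorm(20), n_perm = 200,
                      seed = sample.int(1e6, 1))[["p"]]
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps < 0.25), 0.1)
  expect_gt(mean(ps > 0.75), 0.1)
})

test_that("BY adjustment matches the hand-computed example and dominates BH", {
  adj <- by_fdr(c(0.01, 0.02, 0.04))$adjusted
  # m = 3, c(3) = 1 + 1/2 + 1/3: adjusted = (0.055, 0.055, 0.0733)
  expect_equal(adj, c(0.055, 0.055, 0.07333333), tolerance = 1e-6)
  expect_equal(by_fdr(rep(1, 4))$adjusted, rep(1, 4))
  expect_equal(by_fdr(0.03)$adjusted, 0.03)  # m = 1, c(1) = 1
  set.seed(8)
  p <- runif(50)^2
  expect_true(all(by_fdr(p)$adjusted >= p.adjust(p, "BH") - 1e-12))
  expect_true(all(by_fdr(p)$adjusted >= p))
  expect_error(by_fdr(c(0.5, 1.2)), "outside")
})

test_that("relevance combines FDR significance with the magnitude threshold", {
  scr <- data.frame(pcc = c(0.95, 0.29, 0.4),
                    pcc_p_adj = c(0.001, 0.0001, 0.2))
  out <- relevance_screen(scr)
  expect_identical(out$relevant_pcc, c(TRUE, FALSE, FALSE))
  expect_identical(out$category_pcc, c("very high", "negligible", "low"))
  expect_identical(mukaka_category(c(0, -0.31, 0.5, 0.7, 0.9, 1)),
                   c("negligible", "low", "moderate", "high", "very high",
                     "very high"))
})

test_that("the screen flags the shared-F0 pair and is order-invariant", {
  # small two-group cohort whose GAW and acoustic tracks share pulse trains
  co <- simulate_cohort(c(NF = 16, FDF = 8, NM = 12, FDM = 6), seed = 10)
  params <- extract_cohort(co)
  scr <- run_screen(params, coefficients = "pcc")
  f0row <- scr[scr$gaw_param == "gaw_f0_mean" & scr$acoustic_param == "ac_f0_mean", ]
  expect_equal(nrow(f0row), 2)  # one row per gender
  expect_true(all(f0row$pcc >= 0.9))
  expect_true(all(f0row$relevant_pcc))
  expect_true(all(f0row$category_pcc == "very high"))
  expect_equal(nrow(scr), 2 * 35 * 14)
  # permuting subject order leaves the coefficients unchanged
  set.seed(2)
  scr2 <- run_screen(params[sample(nrow(params)), ], coefficients = "pcc")
  expect_equal(scr2$pcc, scr$pcc)
  # the DCC side of the same screen is deterministic given the seed
  sub <- params[params$group %in% c("NM", "FDM"), ]
  scr_d1 <- run_screen(sub, coefficients = "dcc", n_perm = 200, seed = 5)
  scr_d2 <- run_screen(sub, coefficients = "dcc", n_perm = 200, seed = 5)
  expect_identical(scr_d1$dcc_p_raw, scr_d2$dcc_p_raw)
  expect_true(all(scr_d1$dcc >= 0 & scr_d1$dcc <= 1, na.rm = TRUE))
  f0d <- scr_d1[scr_d1$gaw_param == "gaw_f0_mean" &
                scr_d1$acoustic_param == "ac_f0_mean", ]
  expect_gt(f0d$dcc, 0.9)
})

test_that("norm tables report the declared moment-based statistics", {
  params <- data.frame(subject_id = sprintf("s%d", 1:10),
                       group = rep(c("NF", "NM"), each = 5),
                       gaw_f0_mean = c(-2, -1, 0, 1, 2, rep(7, 5)),
                       ac_f0_mean = c(rnorm(5), 1:5))
  nt <- norm_table(params, groups = c("NF", "NM"))
  row_f <- nt[nt$group == "NF" & nt$parameter == "gaw_f0_mean", ]
  expect_equal(row_f$skewness, 0)
  expect_equal(row_f$mean, 0)
  expect_equal(row_f$median, 0)
  expect_equal(row_f$std, sd(c(-2, -1, 0, 1, 2)))
  expect_true(row_f$minimum <= row_f$median && row_f$median <= row_f$maximum)
  # constant column: zero std, skewness/kurtosis are missing markers
  row_m <- nt[nt$group == "NM" & nt$parameter == "gaw_f0_mean", ]
  expect_equal(row_m$std, 0)
  expect_true(is.na(row_m$skewness) && is.na(row_m$kurtosis))
  # large-sample excess kurtosis of a normal converges to 0
  set.seed(12)
  big <- data.frame(subject_id = sprintf("s%d", 1:10000), group = "NF",
                    gaw_f0_mean = rnorm(10000))
  ntb <- norm_table(big, groups = "NF")
  expect_equal(ntb$kurtosis, 0, tolerance = 0.1)
  expect_equal(ntb$skewness, 0, tolerance = 0.1)
})
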