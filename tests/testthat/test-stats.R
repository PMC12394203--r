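test_that("pearson_with_test matches exact linearity and the formula oracle", {
  x <- 1:10
  expect_equal(pearson_with_test(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_test(x, -x)$r, -1)

  set.seed(13)
  a <- rnorm(20); b <- 0.4 * a + rnorm(20)
  ct <- pearson_with_test(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(18 / (1 - r_hand^2))
  expect_equal(ct$p, 2 * pt(-abs(t_hand), 18), tolerance = 1e-12)

  expect_true(is.na(pearson_with_test(rep(1, 5), 1:5)$r))
  # pairwise deletion of missing pairs
  expect_equal(pearson_with_test(c(a, NA), c(b, 1))$n, 20L)
})

test_that("pearson r is invariant under affine transforms up to sign", {
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  r0 <- pearson_with_test(a, b)$r
  expect_equal(pearson_with_test(3 * a + 5, b)$r, r0)
  expect_equal(pearson_with_test(a, -2 * b + 1)$r, -r0)
})

test_that("Mann-Whitney U handles separation, symmetry and exactness", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  s <- c(1.2, 3.4, 5.6, 7.8)
  expect_equal(mann_whitney_u(s, s)$p, 1, tolerance = 1e-6)

  # 8x8 untied fixture: exact p equals full enumeration over assignments
  set.seed(31)
  a <- rnorm(8); b <- rnorm(8) + 0.8
  mw <- mann_whitney_u(a, b)
  expect_equal(mw$p, brute_mwu(a, b), tolerance = 1e-12)
})

test_that("variance-ratio F statistics reproduce the published values", {
  # cross-species CDR3 length spreads from the bundled summary table
  s <- camelid_cdr3_summary()
  g <- function(sp) s[s$species == sp, ]
  f1 <- f_variance_ratio(g("alpaca")$std, g("alpaca")$count,
                         g("bactrian")$std, g("bactrian")$count)
  expect_equal(round(f1$F, 2), 1.88)
  expect_lt(f1$p, 0.0001)
  f2 <- f_variance_ratio(g("alpaca")$std, g("alpaca")$count,
                         g("human")$std, g("human")$count)
  expect_equal(round(f2$F, 2), 1.46)
  f3 <- f_variance_ratio(g("bactrian")$std, g("bactrian")$count,
                         g("human")$std, g("human")$count)
  expect_equal(round(f3$F, 2), 0.78)

  expect_equal(f_variance_ratio(2, 10, 2, 12)$F, 1)
  # reciprocal statistic
  expect_equal(f_variance_ratio(3.1, 9, 1.7, 14)$F *
                 f_variance_ratio(1.7, 14, 3.1, 9)$F, 1)
  expect_error(f_variance_ratio(0, 5, 1, 5), "must be > 0")
})

test_that("BH adjustment matches step-up arithmetic and is idempotent", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")

  set.seed(8)
  p <- runif(40)^2
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_equal(bh_fdr(adj) >= adj, rep(TRUE, 40))
  # monotone in the sorted order
  expect_true(!is.unsorted(adj[order(p)]))
})

test_that("star codes follow the printed bins with 0.01 closed into **", {
  expect_equal(stars(0.2), "ns")
  expect_equal(stars(0.03), "*")
  expect_equal(stars(0.00005), "****")
  expect_equal(stars(c(0.05, 0.01, 0.001, 0.0005, 0.0001)),
               c("*", "**", "**", "***", "****"))
  expect_true(is.na(stars(NA_real_)))
})

test_that("binned-mean regression fits the line through bin means", {
  x <- rep(1:5, each = 4)
  br <- binned_mean_regression(x, 3 * x)
  expect_equal(br$slope, 3)
  expect_equal(br$intercept, 0, tolerance = 1e-12)

  # unequal bin sizes with equal means leave the line unchanged
  x2 <- c(rep(1, 10), rep(2, 2), rep(3, 5))
  y2 <- c(rep(1, 10), rep(2, 2), rep(3, 5))
  expect_equal(binned_mean_regression(x2, y2)$slope, 1)

  expect_error(binned_mean_regression(rep(1:2, 5), rnorm(10)), ">= 3")

  # planted slope recovered within 3 standard errors
  set.seed(17)
  xs <- sample(8:25, 600, replace = TRUE)
  ys <- 0.7 * xs + rnorm(600, sd = 2)
  brs <- binned_mean_regression(xs, ys)
  se <- tidy(brs)$std.error[2]
  expect_lt(abs(brs$slope - 0.7), 3 * se)
  gl <- glance(brs)
  expect_equal(gl$n_bins, length(unique(xs)))
})
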