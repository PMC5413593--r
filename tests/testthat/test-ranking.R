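# Welch t-test, channel ranking and the KS normality diagnostic.

test_that("Welch t matches hand-computed and reference values", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Welch t reduces to the pooled Student t for balanced equal variances", {
  x <- c(1, 2, 3, 4, 5)
  y <- x + 2  # same variance, shifted
  r <- welch_t(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(pooled$parameter), tolerance = 1e-12)
})

test_that("Welch t is antisymmetric and location/scale equivariant", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9, sd = 2)
    a <- welch_t(x, y); b <- welch_t(y, x)
    expect_identical(a$t, -b$t)
    expect_identical(a$df, b$df)
    shifted <- welch_t(x + 5, y + 5)
    scaled <- welch_t(x * -3, y * -3)
    expect_equal(shifted$t, a$t, tolerance = 1e-9)
    expect_equal(abs(scaled$t), abs(a$t), tolerance = 1e-12)
  }
})

test_that("Welch t enforces its preconditions", {
  expect_error(welch_t(1, c(1, 2)), class = "gse_size_error")
  expect_error(welch_t(c(1, 1, 1), c(2, 2)), class = "gse_degenerate_error")
  # one degenerate group is fine
  expect_silent(welch_t(c(1, 1, 1), c(1, 2, 3)))
})

test_that("sign of t follows the direction of the mean difference", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    r <- welch_t(x, y)
    expect_identical(sign(r$t), sign(r$mean1 - r$mean2))
    expect_true(r$p >= 0 && r$p <= 1 && r$df > 0)
  }
})

test_that("ranking puts significant channels first, ordered by |t|, ties by index", {
  # gaps chosen so significance and |t| ordering are unambiguous
  fm <- make_gap_features(n_per_group = 60,
                          gaps = c(0, 0.12, -0.2, 0.003, 0.30), seed = 2)
  rr <- rank_channels(fm)
  tab <- rr$table
  # significant block strictly precedes the non-significant block
  expect_true(all(diff(tab$significant) <= 0))
  # |t| nonincreasing inside each block
  for (blk in unique(tab$significant)) {
    expect_true(all(diff(abs(tab$t[tab$significant == blk])) <= 1e-12))
  }
  # the three strong channels lead, ordered by separation
  expect_equal(rr$order[1:3], c(5, 3, 2))
  # order is a permutation
  expect_setequal(rr$order, 1:5)
})

test_that("mean-difference ordering mode ranks by |group mean gap|", {
  # channel 2: small gap / tiny variance (big t); channel 3: big gap
  gammaSE:::with_local_seed(5, {
    n <- 80
    v <- cbind(rnorm(2 * n, 0.5, 0.05),
               c(rnorm(n, 0.52, 0.005), rnorm(n, 0.5, 0.005)),
               c(rnorm(n, 0.62, 0.05), rnorm(n, 0.5, 0.05)))
    fm <- feature_matrix(pmin(pmax(v, 0), 1),
                         labels = rep(c("alcoholic", "control"), each = n))
    by_t <- rank_channels(fm, order_by = "t")
    by_gap <- rank_channels(fm, order_by = "mean_diff")
    expect_equal(by_t$order[1], 2)
    expect_equal(by_gap$order[1], 3)
  })
})

test_that("a single planted channel is ranked first", {
  cfg <- synth_config(n_per_group = 200, n_channels = 20,
                      planted_channels = 13, effect = 0.15, seed = 11)
  fm <- build_feature_matrix(generate_epochs(cfg), c(30, 55),
                             filter_spec = filter_spec())
  rr <- rank_channels(fm)
  expect_equal(rr$order[1], 13)
  expect_true(rr$significant[13])
})

test_that("ranking is invariant to epoch order within groups", {
  fm <- make_gap_features(n_per_group = 40, gaps = c(0, 0.1, 0.05, 0),
                          seed = 3)
  perm <- gammaSE:::with_local_seed(1, sample(nrow(fm$values)))
  fm2 <- feature_matrix(fm$values[perm, ], fm$labels[perm],
                        fm$channel_names, fm$band)
  expect_equal(rank_channels(fm2)$order, rank_channels(fm)$order)
  expect_equal(rank_channels(fm2)$table$t, rank_channels(fm)$table$t,
               tolerance = 1e-12)
})

test_that("single-group feature matrices are refused", {
  fm <- feature_matrix(matrix(runif(10), 5, 2), labels = rep("control", 5))
  expect_error(rank_channels(fm), class = "gse_grouping_error")
})

test_that("KS diagnostic separates normal from uniform samples", {
  x_norm <- gammaSE:::with_local_seed(21, rnorm(1000))
  x_unif <- gammaSE:::with_local_seed(21, {
    u <- runif(1000)
    (u - mean(u)) / sd(u)
  })
  kn <- ks_normality(x_norm)
  ku <- ks_normality(x_unif)
  expect_lt(kn$statistic, 0.05)
  expect_gt(ku$statistic, kn$statistic)
  expect_error(ks_normality(c(1, 2, 3, 4)), class = "gse_size_error")
  expect_error(ks_normality(rep(1, 10)), class = "gse_degenerate_error")
})
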