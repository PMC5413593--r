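# k-NN classification, ROC/AUC, stratified holdout and the experiment grid.

test_that("k-NN votes and tie-breaks are deterministic", {
  # coincident test and training point
  tr <- matrix(c(0, 1), ncol = 1)
  lab <- c("control", "alcoholic")
  hit <- knn_classify(tr, lab, matrix(1, 1, 1), k = 1)
  expect_equal(hit$labels, "alcoholic")
  expect_equal(hit$scores, 1)

  # nearest point wins for k = 1
  expect_equal(knn_classify(tr, lab, matrix(0.4, 1, 1), k = 1)$labels,
               "control")

  # distance tie: lower training index wins
  dup <- matrix(c(0, 0), ncol = 1)
  expect_equal(knn_classify(dup, c("alcoholic", "control"),
                            matrix(0, 1, 1), k = 1)$labels, "alcoholic")
  # vote tie: class of the single nearest neighbour
  tie <- knn_classify(matrix(c(0.1, -0.1), ncol = 1),
                      c("control", "alcoholic"), matrix(0.05, 1, 1), k = 2)
  expect_equal(tie$scores, 0.5)
  expect_equal(tie$labels, "control")
})

test_that("k-NN scores are neighbourhood vote fractions", {
  tr <- matrix(c(0, 1, 2, 10), ncol = 1)
  lab <- c("alcoholic", "alcoholic", "control", "control")
  out <- knn_classify(tr, lab, matrix(c(0.2, 9), ncol = 1), k = 3)
  expect_equal(out$scores, c(2 / 3, 1 / 3))
  expect_equal(out$labels, c("alcoholic", "control"))
})

test_that("k = 1 resubstitution is perfect on distinct points", {
  gammaSE:::with_local_seed(10, {
    X <- matrix(rnorm(40), 20, 2)
    lab <- rep(c("alcoholic", "control"), 10)
    out <- knn_classify(X, lab, X, k = 1)
    expect_equal(out$labels, lab)
  })
})

test_that("k-NN enforces its preconditions", {
  X <- matrix(rnorm(6), 3, 2)
  lab <- c("alcoholic", "control", "control")
  expect_error(knn_classify(X[0, , drop = FALSE], character(0), X, k = 1),
               class = "gse_size_error")
  expect_error(knn_classify(X, lab, X, k = 4), class = "gse_param_error")
  expect_error(knn_classify(X, lab, matrix(0, 1, 3), k = 1),
               class = "gse_dimension_error")
})

test_that("ROC endpoints, monotonicity, and closed-form AUC values hold", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1),
                     c("alcoholic", "alcoholic", "control", "control"))
  expect_equal(perfect$auc, 1)

  flat <- roc_auc(rep(0.5, 6), rep(c("alcoholic", "control"), 3))
  expect_equal(flat$auc, 0.5)

  mixed <- roc_auc(c(0.9, 0.8, 0.3), c("alcoholic", "control", "control"))
  expect_equal(mixed$auc, 1)

  r <- roc_auc(c(0.2, 0.7, 0.7, 0.4, 0.9, 0.1),
               c("control", "alcoholic", "control", "alcoholic",
                 "alcoholic", "control"))
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))

  expect_error(roc_auc(c(0.1, 0.2), c("control", "control")),
               class = "gse_degenerate_error")
})

test_that("AUC equals the Mann-Whitney concordance probability", {
  gammaSE:::with_local_seed(12, {
    for (i in 1:10) {
      n <- 40
      truth <- sample(rep(c("alcoholic", "control"), n / 2))
      scores <- round(runif(n), 2)  # force some ties
      pos <- scores[truth == "alcoholic"]
      neg <- scores[truth == "control"]
      conc <- mean(outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b)))
      expect_equal(roc_auc(scores, truth)$auc, conc, tolerance = 1e-9)
    }
  })
})

test_that("holdout evaluation is stratified, seeded and reproducible", {
  fm <- make_gap_features(n_per_group = 40, gaps = c(0.3, 0, 0, 0), seed = 4)
  r1 <- holdout_evaluate(fm, n_channels = 4, n_pcs = 2, seed = 3)
  r2 <- holdout_evaluate(fm, n_channels = 4, n_pcs = 2, seed = 3)
  expect_identical(r1[c("tp", "fp", "tn", "fn", "efficiency", "auc")],
                   r2[c("tp", "fp", "tn", "fn", "efficiency", "auc")])
  expect_equal(r1$n_train, 40)
  expect_equal(r1$n_test, 40)
  expect_equal(r1$tp + r1$fp + r1$tn + r1$fn, r1$n_test)
  # strong single-channel signal classifies well above chance
  expect_gt(r1$efficiency, 0.9)
  # sensitivity/specificity consistent with the confusion counts
  expect_equal(r1$sensitivity, r1$tp / (r1$tp + r1$fn))
  expect_equal(r1$specificity, r1$tn / (r1$tn + r1$fp))
})

test_that("holdout evaluation rejects out-of-range subset sizes", {
  fm <- make_gap_features(n_per_group = 10, gaps = c(0, 0), seed = 1)
  expect_error(holdout_evaluate(fm, n_channels = 3, n_pcs = 1),
               class = "gse_param_error")
  expect_error(holdout_evaluate(fm, n_channels = 2, n_pcs = 3),
               class = "gse_param_error")
  expect_error(holdout_evaluate(fm, n_channels = 2, n_pcs = 1, split = 1),
               class = "gse_param_error")
})

test_that("null features classify at chance level", {
  cfg <- synth_config(n_per_group = 300, n_channels = 16, effect = 0,
                      seed = 5)
  fm <- build_feature_matrix(generate_epochs(cfg), c(30, 55),
                             filter_spec = filter_spec())
  effs <- vapply(1:20, function(s) {
    holdout_evaluate(fm, n_channels = 16, n_pcs = 5, k = 3,
                     seed = s)$efficiency
  }, numeric(1))
  expect_true(all(effs >= 0.42 & effs <= 0.58))
  expect_lt(abs(mean(effs) - 0.5), 0.03)
})

test_that("planted signal yields high ranked-subset efficiency", {
  planted <- c(16, 18, 20, 22, 24, 26, 28, 30, 32, 34)
  cfg <- synth_config(n_per_group = 300, n_channels = 35,
                      planted_channels = planted, effect = 0.2, seed = 6)
  fm <- build_feature_matrix(generate_epochs(cfg), c(30, 55),
                             filter_spec = filter_spec())
  effs <- vapply(1:5, function(s) {
    holdout_evaluate(fm, n_channels = 15, n_pcs = 15, ranked = TRUE,
                     k = 3, seed = s)$efficiency
  }, numeric(1))
  expect_gte(mean(effs), 0.85)
})

test_that("the experiment grid is complete, deterministic and annotated", {
  fm <- make_gap_features(n_per_group = 30,
                          gaps = c(0.2, rep(0, 7)), seed = 13)
  grids <- list(`8` = c(2, 4, 8), `4` = c(2, 4))
  gr <- run_grid(fm, Ns = c(8, 4), pcs_by_N = grids, k = 3, seeds = 1:2)
  expect_equal(nrow(gr), 2 * 2 * (3 + 2))
  gr2 <- run_grid(fm, Ns = c(8, 4), pcs_by_N = grids, k = 3, seeds = 1:2)
  expect_equal(gr, gr2)
  # invalid d grids are refused up front
  expect_error(run_grid(fm, Ns = 4, pcs_by_N = list(`4` = c(2, 5)),
                        seeds = 1),
               class = "gse_param_error")
  # failures inside a cell carry their grid coordinates
  fm_small <- make_gap_features(n_per_group = 2, gaps = rep(0, 4), seed = 1)
  expect_error(
    run_grid(fm_small, Ns = 4, pcs_by_N = list(`4` = 2), seeds = 1),
    "N=4.*seed=1", class = "gse_grid_error"
  )
  # pivot has one row per (N, d) with both modes side by side
  pv <- pivot_grid(gr)
  expect_equal(nrow(pv), 5)
  expect_true(all(c("efficiency_pct_norank", "efficiency_pct_rank")
                  %in% names(pv)))
})

test_that("selecting all channels makes ranking a pure permutation", {
  fm <- make_gap_features(n_per_group = 40, gaps = c(0.1, 0, 0.05, 0, 0),
                          seed = 14)
  a <- holdout_evaluate(fm, n_channels = 5, n_pcs = 3, ranked = TRUE,
                        seed = 2)
  b <- holdout_evaluate(fm, n_channels = 5, n_pcs = 3, ranked = FALSE,
                        seed = 2)
  expect_identical(a[c("tp", "fp", "tn", "fn", "efficiency", "auc")],
                   b[c("tp", "fp", "tn", "fn", "efficiency", "auc")])
})

test_that("consistently relabelling channels leaves reports unchanged", {
  fm <- make_gap_features(n_per_group = 40, gaps = c(0.15, 0, 0.08, 0, 0, 0),
                          seed = 15)
  perm <- c(4, 1, 6, 3, 2, 5)
  fm_p <- feature_matrix(fm$values[, perm], fm$labels,
                         fm$channel_names[perm], fm$band)
  a <- holdout_evaluate(fm, n_channels = 3, n_pcs = 2, ranked = TRUE,
                        seed = 7)
  b <- holdout_evaluate(fm_p, n_channels = 3, n_pcs = 2, ranked = TRUE,
                        seed = 7)
  expect_equal(a$efficiency, b$efficiency)
  expect_equal(a$auc, b$auc)
  expect_equal(a[c("tp", "fp", "tn", "fn")], b[c("tp", "fp", "tn", "fn")])
  # the same channels were selected, up to the relabelling
  expect_setequal(perm[b$selected], a$selected)
})

test_that("efficiency grows with components when discriminative variance is low", {
  # group difference planted in channels whose entropy variance (including
  # the group shift itself) stays below the variance of the other channels,
  # so principal components pick the signal up only at larger dimension
  planted <- c(14, 17)
  cfg <- synth_config(n_per_group = 150, n_channels = 20,
                      planted_channels = planted, effect = 0.08,
                      base_complexity = 0.5, planted_base_complexity = 0.12,
                      seed = 16)
  fm <- build_feature_matrix(generate_epochs(cfg), c(30, 55),
                             filter_spec = filter_spec())
  gr <- run_grid(fm, Ns = 20, pcs_by_N = list(`20` = c(2, 8, 14, 20)),
                 ranked_modes = FALSE, k = 3, seeds = 1:6)
  m <- stats::aggregate(efficiency ~ n_pcs, gr, mean)
  expect_gt(cor(m$n_pcs, m$efficiency, method = "spearman"), 0)
  expect_gt(m$efficiency[4], m$efficiency[1] + 0.2)
})
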