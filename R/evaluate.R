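# Classification and evaluation: k-NN on PCA scores, stratified holdout,
# ROC/AUC, and the ranked vs non-ranked x N x d experiment grid.

#' k-nearest-neighbour classification
#'
#' Labels each test point by majority vote among its `k` nearest training
#' points under the Euclidean metric. The positive-class score of a test
#' point is the fraction of its `k` neighbours labelled `"alcoholic"`.
#' Deterministic tie handling: equal distances are resolved in favour of
#' the lower training-point index, and an even vote goes to the class of
#' the single nearest neighbour.
#'
#' @param train_x numeric training matrix (rows are points).
#' @param train_labels group labels of the training rows.
#' @param test_x numeric test matrix with the same column count.
#' @param k number of neighbours, `1 <= k <= nrow(train_x)`.
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @return list with `labels` (predicted group per test row) and `scores`
#'   (positive-class score per test row).
#' @export
knn_classify <- function(train_x, train_labels, test_x, k = 3,
                         metric = c("euclidean")) {
  metric <- match.arg(metric)
  if (!is.matrix(train_x)) train_x <- as.matrix(train_x)
  if (!is.matrix(test_x)) test_x <- as.matrix(test_x)
  n_train <- nrow(train_x)
  if (n_train < 1L) {
    gse_stop("empty training set", "gse_size_error")
  }
  if (length(train_labels) != n_train) {
    gse_stop("one label per training row required", "gse_param_error")
  }
  train_labels <- check_labels(train_labels)
  if (!is_count(k) || k < 1L || k > n_train) {
    gse_stop(sprintf("`k` must lie in 1..%d", n_train), "gse_param_error")
  }
  if (ncol(test_x) != ncol(train_x)) {
    gse_stop("train and test dimensionality differ", "gse_dimension_error")
  }
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(test_x^2), rep(1, n_train)) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  d2[d2 < 0] <- 0
  pos <- train_labels == GSE_GROUPS[1L]
  labels <- character(nrow(test_x))
  scores <- numeric(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nb <- order(d2[i, ])[seq_len(k)]  # stable: lower index wins ties
    s <- mean(pos[nb])
    labels[i] <- if (s > 0.5) GSE_GROUPS[1L]
      else if (s < 0.5) GSE_GROUPS[2L]
      else train_labels[nb[1L]]
    scores[i] <- s
  }
  list(labels = labels, scores = scores)
}

#' ROC curve and AUC from positive-class scores
#'
#' Sweeps the decision threshold over the distinct score values and traces
#' the (false-positive rate, true-positive rate) curve from (0, 0) to
#' (1, 1); the area under the curve is computed by the trapezoid rule,
#' which for tied and untied scores alike equals the Mann-Whitney
#' concordance probability (ties counted half).
#'
#' @param scores numeric positive-class scores.
#' @param truth true group labels; both groups must be present.
#' @return list with `roc` (data frame of `fpr`, `tpr` in sweep order) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- check_labels(truth)
  pos <- truth == GSE_GROUPS[1L]
  if (!any(pos) || all(pos)) {
    gse_stop("both classes must be present to trace a ROC curve",
             "gse_degenerate_error")
  }
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1L))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1L))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  roc <- unique(roc)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Single stratified holdout evaluation
#'
#' One end-to-end evaluation run: a seeded stratified split into training
#' and test partitions, channel-subset selection (the first `n_channels`
#' of the t-test ranking, or the first `n_channels` in native dataset
#' order), PCA reduction to `n_pcs` components, k-NN classification, and
#' metric computation with `"alcoholic"` as the positive class.
#'
#' To avoid information leakage, both the channel ranking and the PCA basis
#' are by default computed on the training partition only and then applied
#' unchanged to the test partition (`rank_scope = "train"`,
#' `pca_scope = "train"`). The `"pooled"` scopes reproduce the
#' whole-dataset variant instead. The selected channel subset is treated
#' as a set: its columns enter PCA in ascending channel order, so a
#' selection that permutes all channels is exactly equivalent to using the
#' native order.
#'
#' @param fm a [feature_matrix] with both groups present.
#' @param n_channels number of channels to keep (N).
#' @param n_pcs number of principal components (d), `d <= N`.
#' @param ranked logical: rank channels by the Welch t-test before taking
#'   the first N? Otherwise the first N channels in native order are used.
#' @param k neighbours for the k-NN vote (default 3; odd values avoid most
#'   vote ties).
#' @param split training fraction of the stratified holdout (default 0.5).
#' @param seed seed of the split.
#' @param rank optional precomputed [rank_channels()] result to use in
#'   ranked mode (overrides `rank_scope`).
#' @param rank_scope `"train"` (default) or `"pooled"`: data used to
#'   compute the ranking in ranked mode.
#' @param pca_scope `"train"` (default) or `"pooled"`: data used to fit
#'   the PCA basis.
#' @param alpha significance gate for the ranking.
#' @return An object of class `classification_report`: confusion counts
#'   (`tp`, `fp`, `tn`, `fn`), `efficiency` (accuracy fraction),
#'   `sensitivity`, `specificity`, `roc`, `auc`, the `selected` channel
#'   subset, and the partition sizes.
#' @export
holdout_evaluate <- function(fm, n_channels, n_pcs, ranked = FALSE, k = 3,
                             split = 0.5, seed = 1, rank = NULL,
                             rank_scope = c("train", "pooled"),
                             pca_scope = c("train", "pooled"),
                             alpha = 0.05) {
  validate_feature_matrix(fm)
  rank_scope <- match.arg(rank_scope)
  pca_scope <- match.arg(pca_scope)
  C <- ncol(fm$values)
  if (!(split > 0 && split < 1)) {
    gse_stop("`split` must lie strictly between 0 and 1", "gse_param_error")
  }
  if (!is_count(n_channels) || n_channels < 1L || n_channels > C) {
    gse_stop(sprintf("`n_channels` must lie in 1..%d", C), "gse_param_error")
  }
  if (!is_count(n_pcs) || n_pcs < 1L || n_pcs > n_channels) {
    gse_stop("`n_pcs` must lie in 1..n_channels", "gse_param_error")
  }
  g1 <- which(fm$labels == GSE_GROUPS[1L])
  g2 <- which(fm$labels == GSE_GROUPS[2L])
  if (length(g1) < 2L || length(g2) < 2L) {
    gse_stop("both groups must be present with at least 2 epochs each",
             "gse_grouping_error")
  }

  idx <- with_local_seed(seed, {
    take <- function(g) sample(g)[seq_len(max(1L, round(length(g) * split)))]
    sort(c(take(g1), take(g2)))
  })
  train <- idx
  test <- setdiff(seq_len(nrow(fm$values)), train)

  sub_fm <- function(rows) {
    feature_matrix(fm$values[rows, , drop = FALSE], fm$labels[rows],
                   fm$channel_names, fm$band)
  }
  if (ranked) {
    r <- if (!is.null(rank)) rank
      else if (rank_scope == "train") rank_channels(sub_fm(train), alpha = alpha)
      else rank_channels(fm, alpha = alpha)
    sel <- r$order[seq_len(n_channels)]
  } else {
    sel <- seq_len(n_channels)
  }
  sel <- sort(sel)

  fit_rows <- if (pca_scope == "train") train else seq_len(nrow(fm$values))
  model <- fit_pca(fm$values[fit_rows, sel, drop = FALSE])
  tr_y <- pca_transform(model, fm$values[train, sel, drop = FALSE], n_pcs)
  te_y <- pca_transform(model, fm$values[test, sel, drop = FALSE], n_pcs)

  pred <- knn_classify(tr_y, fm$labels[train], te_y, k = k)
  truth <- fm$labels[test]
  tp <- sum(pred$labels == GSE_GROUPS[1L] & truth == GSE_GROUPS[1L])
  fp <- sum(pred$labels == GSE_GROUPS[1L] & truth == GSE_GROUPS[2L])
  tn <- sum(pred$labels == GSE_GROUPS[2L] & truth == GSE_GROUPS[2L])
  fn <- sum(pred$labels == GSE_GROUPS[2L] & truth == GSE_GROUPS[1L])
  ra <- roc_auc(pred$scores, truth)
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      efficiency = (tp + tn) / length(test),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      roc = ra$roc, auc = ra$auc,
      selected = sel, n_train = length(train), n_test = length(test),
      k = k, seed = seed, ranked = ranked, n_channels = n_channels,
      n_pcs = n_pcs
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    paste0("<classification_report> N=%d channels (%s), d=%d pcs, k=%d\n",
           "  efficiency %.4f | sensitivity %.4f | specificity %.4f | AUC %.4f\n",
           "  confusion: tp=%d fp=%d tn=%d fn=%d (test n=%d)\n"),
    x$n_channels, if (x$ranked) "ranked" else "native order", x$n_pcs, x$k,
    x$efficiency, x$sensitivity, x$specificity, x$auc,
    x$tp, x$fp, x$tn, x$fn, x$n_test
  ))
  invisible(x)
}

#' Run the ranked/non-ranked x N x d experiment grid
#'
#' Full factorial over channel-subset size `N`, component count `d`,
#' ranking mode and split seed, calling [holdout_evaluate()] for every
#' combination. Errors are annotated with their grid coordinates.
#'
#' @param fm a [feature_matrix].
#' @param Ns integer vector of channel-subset sizes (the reference study
#'   uses 61, 25 and 15).
#' @param pcs_by_N named list mapping each `N` (as a name) to the d-grid to
#'   evaluate at that size; every d must satisfy `d <= N`.
#' @param ranked_modes logical vector of ranking modes to run.
#' @param k,split,rank_scope,pca_scope,alpha passed to
#'   [holdout_evaluate()].
#' @param seeds integer vector of holdout split seeds.
#' @return A long-format data frame of class `grid_result`, one row per
#'   (N, ranked, d, seed) with the scalar metrics of each run.
#' @seealso [pivot_grid()] for the mean-over-seeds pivot table.
#' @export
run_grid <- function(fm, Ns = c(61, 25, 15),
                     pcs_by_N = list(`61` = c(5, 15, 25, 45, 61),
                                     `25` = c(5, 15, 25),
                                     `15` = c(5, 15)),
                     ranked_modes = c(TRUE, FALSE), k = 3, split = 0.5,
                     seeds = 1:5, rank_scope = "train",
                     pca_scope = "train", alpha = 0.05) {
  for (N in Ns) {
    d_grid <- pcs_by_N[[as.character(N)]]
    if (is.null(d_grid)) {
      gse_stop(sprintf("pcs_by_N has no entry for N = %d", N),
               "gse_param_error")
    }
    if (any(d_grid > N)) {
      gse_stop(sprintf("d grid for N = %d contains d > N", N),
               "gse_param_error")
    }
  }
  rows <- list()
  for (seed in seeds) {
    for (ranked in ranked_modes) {
      for (N in Ns) {
        for (d in pcs_by_N[[as.character(N)]]) {
          rep <- tryCatch(
            holdout_evaluate(fm, n_channels = N, n_pcs = d, ranked = ranked,
                             k = k, split = split, seed = seed,
                             rank_scope = rank_scope, pca_scope = pca_scope,
                             alpha = alpha),
            error = function(e) {
              gse_stop(sprintf(
                "grid cell (N=%d, ranked=%s, d=%d, seed=%d) failed: %s",
                N, ranked, d, seed, conditionMessage(e)
              ), "gse_grid_error")
            }
          )
          rows[[length(rows) + 1L]] <- data.frame(
            n_channels = N, ranked = ranked, n_pcs = d, seed = seed,
            efficiency = rep$efficiency, sensitivity = rep$sensitivity,
            specificity = rep$specificity, auc = rep$auc
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_result", class(out))
  out
}

#' Pivot a grid result into the mean-over-seeds performance table
#'
#' Averages the long-format [run_grid()] output over seeds and reshapes it
#' into one row per (N, d) with side-by-side non-ranked and ranked metric
#' columns, mirroring the layout of published k-NN performance tables
#' (efficiency as a percentage, sensitivity and specificity as fractions).
#'
#' @param grid a `grid_result` from [run_grid()].
#' @return data frame with columns `n_channels`, `n_pcs` and, per mode,
#'   `efficiency_pct`, `sensitivity`, `specificity` (suffix `_norank` /
#'   `_rank`).
#' @export
pivot_grid <- function(grid) {
  agg <- stats::aggregate(
    grid[, c("efficiency", "sensitivity", "specificity")],
    by = list(n_channels = grid$n_channels, ranked = grid$ranked,
              n_pcs = grid$n_pcs),
    FUN = mean
  )
  agg$efficiency_pct <- 100 * agg$efficiency
  shape <- function(mode, suffix) {
    sub <- agg[agg$ranked == mode,
               c("n_channels", "n_pcs", "efficiency_pct", "sensitivity",
                 "specificity")]
    names(sub)[3:5] <- paste0(names(sub)[3:5], suffix)
    sub
  }
  out <- merge(shape(FALSE, "_norank"), shape(TRUE, "_rank"),
               by = c("n_channels", "n_pcs"), all = TRUE)
  out[order(-out$n_channels, out$n_pcs), , drop = FALSE]
}
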