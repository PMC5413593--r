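# Principal component analysis via the explicit covariance route:
# mean-centering, V = X^T X / (N - 1), symmetric eigendecomposition,
# top-d projection. Written out rather than delegated so the covariance
# convention and sign fixing are exactly as documented; an SVD-based
# computation serves as the independent cross-check in the test suite.

#' Fit a principal component model
#'
#' Centers each column (channel) at its mean, forms the unbiased covariance
#' matrix `V = t(Xc) %*% Xc / (N - 1)` and eigendecomposes it. Eigenvalues
#' are returned in descending order with tiny negative rounding clamped to
#' zero; eigenvectors are orthonormal with a deterministic sign convention
#' (the largest-magnitude entry of each component is positive).
#'
#' @param features numeric sample-by-channel matrix (>= 2 rows).
#' @return An object of class `pca_model`: `mean` (per-channel means),
#'   `components` (orthonormal columns, by descending eigenvalue),
#'   `eigenvalues` and `n_fit`.
#' @export
fit_pca <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  N <- nrow(features)
  if (N < 2L) {
    gse_stop("need at least 2 samples to fit a PCA model", "gse_size_error")
  }
  if (ncol(features) < 1L) {
    gse_stop("need at least 1 channel to fit a PCA model", "gse_size_error")
  }
  mu <- colMeans(features)
  Xc <- sweep(features, 2L, mu)
  V <- crossprod(Xc) / (N - 1)
  e <- eigen(V, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  W <- e$vectors
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(
    list(mean = mu, components = W, eigenvalues = vals, n_fit = N),
    class = "pca_model"
  )
}

#' Project features onto the leading principal components
#'
#' Applies the fitted transform `Y = (X - mean) %*% components[, 1:d]`.
#' Held-out data must be projected with the training-fit model; no
#' refitting happens here.
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param features sample-by-channel matrix with the same channel count the
#'   model was fitted on.
#' @param d number of leading components to keep,
#'   `1 <= d <= ncol(model$components)`.
#' @return sample-by-`d` score matrix.
#' @export
pca_transform <- function(model, features, d) {
  if (!inherits(model, "pca_model")) {
    gse_stop("`model` must come from fit_pca()", "gse_param_error")
  }
  if (!is.matrix(features)) features <- as.matrix(features)
  if (!is_count(d) || d < 1L || d > ncol(model$components)) {
    gse_stop(sprintf("`d` must lie in 1..%d", ncol(model$components)),
             "gse_dimension_error")
  }
  if (ncol(features) != length(model$mean)) {
    gse_stop(sprintf(
      "feature column count (%d) does not match the fitted model (%d)",
      ncol(features), length(model$mean)
    ), "gse_dimension_error")
  }
  sweep(features, 2L, model$mean) %*% model$components[, seq_len(d), drop = FALSE]
}

#' Serialize / restore a PCA model as delimited text
#'
#' Audit-friendly plain-text persistence: mean vector, eigenvalues and the
#' component matrix at full precision.
#'
#' @param model a `pca_model`.
#' @param path destination / source file path.
#' @export
write_pca_model <- function(model, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  writeLines(c(
    "# gammaSE-pca v1",
    sprintf("# n_fit\t%d", model$n_fit),
    paste0("mean\t", num(model$mean)),
    paste0("eigenvalues\t", num(model$eigenvalues))
  ), con)
  for (j in seq_len(ncol(model$components))) {
    writeLines(paste0("component\t", num(model$components[, j])), con)
  }
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1L] != "# gammaSE-pca v1") {
    gse_stop(sprintf("%s is not a gammaSE PCA file", path), "gse_parse_error")
  }
  n_fit <- as.integer(sub("^# n_fit\t", "",
                          lines[startsWith(lines, "# n_fit")]))
  nums <- function(prefix) {
    rows <- lines[startsWith(lines, paste0(prefix, "\t"))]
    lapply(strsplit(sub(paste0("^", prefix, "\t"), "", rows), "\t"),
           as.numeric)
  }
  comps <- nums("component")
  structure(
    list(mean = nums("mean")[[1L]],
         components = do.call(cbind, comps),
         eigenvalues = nums("eigenvalues")[[1L]],
         n_fit = n_fit),
    class = "pca_model"
  )
}
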