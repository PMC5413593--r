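#' Labelled multichannel EEG epochs
#'
#' An `epoch_set` bundles a tensor of fixed-length multichannel EEG epochs
#' with their group labels and sampling metadata. The data tensor is indexed
#' `[epoch, channel, sample]` and holds amplitudes in microvolts. Every epoch
#' carries exactly one group label, either `"alcoholic"` or `"control"`.
#'
#' The number of samples per epoch must equal `round(fs * duration_s)`;
#' channel names must be unique and match the channel dimension. Channel
#' indices are 1-based everywhere in this package, which also matches the
#' 1-based channel numbering conventional in published electrode tables.
#'
#' @param data numeric array with dimensions
#'   `c(n_epochs, n_channels, n_samples)`, in microvolts.
#' @param labels character vector of per-epoch group tags, one of
#'   `"alcoholic"` or `"control"`; length `n_epochs`.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of unique channel names; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param duration_s epoch length in seconds; defaults to
#'   `n_samples / fs`.
#'
#' @return An object of class `epoch_set`: a list with elements `data`,
#'   `labels`, `fs`, `channel_names`, `duration_s`.
#' @examples
#' es <- epoch_set(array(rnorm(2 * 3 * 64), c(2, 3, 64)),
#'                 labels = c("alcoholic", "control"), fs = 64)
#' dim(es$data)
#' @export
epoch_set <- function(data, labels, fs, channel_names = NULL, duration_s = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    gse_stop("`data` must be a 3-d array [epoch, channel, sample]",
             "gse_param_error")
  }
  n_samples <- dim(data)[3L]
  if (is.null(duration_s)) duration_s <- n_samples / fs
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2L]))
  }
  es <- structure(
    list(
      data = data,
      labels = as.character(labels),
      fs = fs,
      channel_names = as.character(channel_names),
      duration_s = duration_s
    ),
    class = "epoch_set"
  )
  validate_epoch_set(es)
  es
}

#' Validate the invariants of an `epoch_set`
#'
#' Checks tensor shape, label values and count, channel-name uniqueness, and
#' the `samples == round(fs * duration_s)` consistency. Called by every
#' function that consumes or writes an `epoch_set`.
#'
#' @param es object to validate.
#' @return `es`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_epoch_set <- function(es) {
  if (!inherits(es, "epoch_set")) {
    gse_stop("not an epoch_set object", "gse_param_error")
  }
  d <- dim(es$data)
  if (length(d) != 3L) {
    gse_stop("epoch data must be a 3-d array", "gse_param_error")
  }
  if (!is.numeric(es$fs) || length(es$fs) != 1L || es$fs <= 0) {
    gse_stop("`fs` must be a single positive number", "gse_param_error")
  }
  if (d[3L] != round(es$fs * es$duration_s)) {
    gse_stop(sprintf(
      "samples per epoch (%d) != round(fs * duration_s) = %d",
      d[3L], round(es$fs * es$duration_s)
    ), "gse_param_error")
  }
  if (length(es$channel_names) != d[2L]) {
    gse_stop("length(channel_names) must equal the channel dimension",
             "gse_param_error")
  }
  if (anyDuplicated(es$channel_names)) {
    gse_stop("channel names must be unique", "gse_param_error")
  }
  if (length(es$labels) != d[1L]) {
    gse_stop("every epoch needs exactly one label", "gse_param_error")
  }
  check_labels(es$labels)
  invisible(es)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples (%.6g Hz, %.6g s)\n",
    d[1L], d[2L], d[3L], x$fs, x$duration_s
  ))
  if (d[1L] > 0) {
    tab <- table(factor(x$labels, levels = GSE_GROUPS))
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' Per-epoch, per-channel spectral entropy features
#'
#' A `feature_matrix` holds the normalized spectral entropy of each channel
#' of each epoch, computed over a frequency band, together with the group
#' labels. Rows are epochs (samples), columns are channels; all values lie
#' in \[0, 1\].
#'
#' @param values numeric matrix `[epoch, channel]` of spectral entropies.
#' @param labels character vector of per-epoch group tags.
#' @param channel_names unique channel names, one per column.
#' @param band numeric length-2 vector, the band `(f1, f2)` in Hz the
#'   entropies were computed over.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, channel_names = NULL,
                           band = c(30, 55)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    gse_stop("`values` must be a numeric matrix [epoch, channel]",
             "gse_param_error")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(ncol(values)))
  }
  fm <- structure(
    list(
      values = unname(values),
      labels = as.character(labels),
      channel_names = as.character(channel_names),
      band = as.numeric(band)
    ),
    class = "feature_matrix"
  )
  validate_feature_matrix(fm)
  fm
}

#' @rdname feature_matrix
#' @param fm object to validate.
#' @export
validate_feature_matrix <- function(fm) {
  if (!inherits(fm, "feature_matrix")) {
    gse_stop("not a feature_matrix object", "gse_param_error")
  }
  if (nrow(fm$values) != length(fm$labels)) {
    gse_stop("row count must equal label count", "gse_param_error")
  }
  if (length(fm$channel_names) != ncol(fm$values) ||
      anyDuplicated(fm$channel_names)) {
    gse_stop("channel names must be unique and match the column count",
             "gse_param_error")
  }
  if (nrow(fm$values) > 0 &&
      (anyNA(fm$values) || min(fm$values) < -1e-12 || max(fm$values) > 1 + 1e-12)) {
    gse_stop("spectral entropy values must lie in [0, 1]", "gse_param_error")
  }
  check_labels(fm$labels)
  if (length(fm$band) != 2L || fm$band[1] >= fm$band[2]) {
    gse_stop("`band` must be an increasing pair (f1, f2)", "gse_param_error")
  }
  invisible(fm)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d epochs x %d channels, band %.6g-%.6g Hz\n",
    nrow(x$values), ncol(x$values), x$band[1], x$band[2]
  ))
  invisible(x)
}
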