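# Normalized spectral entropy features.
#
# The power spectral density estimator is a single-window magnitude-squared
# FFT periodogram of the full epoch: no taper, no segment averaging. For the
# canonical 1-s, 256-sample epochs this yields exactly 1 Hz bins, so the
# closed 30--55 Hz band contains 26 bin-aligned frequencies.

#' One-sided periodogram of a single trace
#'
#' Magnitude-squared FFT periodogram with the one-sided doubling convention
#' (all bins except DC and, for even lengths, Nyquist are doubled), so that
#' the summed one-sided power equals the total signal energy `sum(x^2)`
#' (Parseval's identity).
#'
#' @param x numeric vector of samples (length >= 2).
#' @param fs sampling rate in Hz.
#' @return An object of class `gse_spectrum`: a list with `freqs` (Hz,
#'   `0 .. fs/2`), `power` (nonnegative, microvolt^2 scale) and
#'   `resolution_hz = fs / length(x)`.
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2L) {
    gse_stop("need at least 2 samples for a spectrum", "gse_size_error")
  }
  X <- stats::fft(as.numeric(x))
  half <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(half)])^2 / n
  # one-sided doubling: everything except DC and (even n) Nyquist
  dbl <- rep(2, half)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[half] <- 1
  p <- p * dbl
  structure(
    list(
      freqs = (seq_len(half) - 1L) * fs / n,
      power = p,
      resolution_hz = fs / n
    ),
    class = "gse_spectrum"
  )
}

#' Normalized spectral entropy over a frequency band
#'
#' Shannon entropy of the in-band power distribution, normalized to
#' \[0, 1\]: the bins with `f1 <= f <= f2` (closed interval) are selected,
#' their powers are normalized to probabilities
#' `P_n(f_i) = P(f_i) / sum(P)`, and
#' `SE = -(1 / log N) * sum(P_n * log(P_n))` where `N` is the number of
#' selected bins. A spectrum with all power in one bin gives 0; a uniform
#' in-band spectrum gives 1. Zero-power bins contribute 0 (the
#' `x * log(x) -> 0` limit). The value is invariant to overall power
#' scaling and to the base of the logarithm.
#'
#' @param sp a `gse_spectrum` from [power_spectrum()].
#' @param band numeric length-2 vector `(f1, f2)` in Hz.
#' @return spectral entropy in \[0, 1\].
#' @export
spectral_entropy <- function(sp, band = c(30, 55)) {
  if (!inherits(sp, "gse_spectrum")) {
    gse_stop("`sp` must come from power_spectrum()", "gse_param_error")
  }
  sel <- sp$freqs >= band[1L] - 1e-9 & sp$freqs <= band[2L] + 1e-9
  nb <- sum(sel)
  if (nb < 2L) {
    gse_stop(sprintf("band [%g, %g] Hz contains %d spectral bins; need >= 2",
                     band[1L], band[2L], nb), "gse_band_error")
  }
  p <- sp$power[sel]
  tot <- sum(p)
  if (tot <= 0) {
    gse_stop("all-zero in-band power: spectral entropy undefined",
             "gse_degenerate_error")
  }
  pn <- p / tot
  nz <- pn > 0
  -sum(pn[nz] * log(pn[nz])) / log(nb)
}

# Vectorized spectral entropy of many traces (columns of X). Same estimator
# as power_spectrum() + spectral_entropy(), but the periodogram ordinates
# are evaluated only at the in-band DFT bins, as one cosine/sine basis
# matrix product over all traces (the explicit DFT at those bins). Returns
# a vector of entropies; traces with zero in-band power yield NA (callers
# attach coordinates to the error).
.se_matrix <- function(X, fs, band) {
  n <- nrow(X)
  half <- floor(n / 2) + 1L
  freqs <- (seq_len(half) - 1L) * fs / n
  sel <- which(freqs >= band[1L] - 1e-9 & freqs <= band[2L] + 1e-9)
  nb <- length(sel)
  if (nb < 2L) {
    gse_stop(sprintf("band [%g, %g] Hz contains %d spectral bins; need >= 2",
                     band[1L], band[2L], nb), "gse_band_error")
  }
  ang <- outer(sel - 1L, seq_len(n) - 1L) * (2 * pi / n)
  re <- cos(ang) %*% X
  im <- sin(ang) %*% X
  dbl <- rep(2, nb)
  dbl[sel == 1L] <- 1
  if (n %% 2L == 0L) dbl[sel == half] <- 1
  P <- (re^2 + im^2) / n * dbl
  tot <- colSums(P)
  se <- rep(NA_real_, ncol(P))
  ok <- tot > 0
  if (any(ok)) {
    Pn <- P[, ok, drop = FALSE] / rep(tot[ok], each = nb)
    L <- Pn * log(Pn)
    L[Pn == 0] <- 0
    se[ok] <- -colSums(L) / log(nb)
  }
  se
}

#' Build the spectral entropy feature matrix of an epoch set
#'
#' Computes the normalized spectral entropy of every (epoch, channel) trace
#' over `band` and assembles the epochs-by-channels [feature_matrix], with
#' labels carried through unchanged. Epochs are rows, so a study of 1200
#' epochs over 61 channels yields a 1200 x 61 matrix.
#'
#' The canonical pipeline filters first ([extract_gamma()]) and then
#' computes entropies on the filtered epochs; passing `filter_spec` here
#' fuses the two steps (identical result, one pass over the data). With
#' `filter_spec = NULL` the entropies are computed on the epochs as given,
#' which restricts to the band's spectral bins without filtering - useful
#' for sensitivity analysis of the filtering step.
#'
#' @param es an [epoch_set] with at least one epoch.
#' @param band numeric length-2 vector `(f1, f2)` in Hz.
#' @param filter_spec optional [filter_spec()]; when supplied, every trace
#'   is zero-phase filtered (as in [extract_gamma()]) before its spectrum
#'   is taken.
#' @return a [feature_matrix].
#' @export
build_feature_matrix <- function(es, band = c(30, 55), filter_spec = NULL) {
  validate_epoch_set(es)
  d <- dim(es$data)
  if (d[1L] == 0L) {
    gse_stop("epoch set is empty", "gse_size_error")
  }
  X <- matrix(aperm(es$data, c(3L, 2L, 1L)), nrow = d[3L])
  if (!is.null(filter_spec)) {
    if (!isTRUE(all.equal(es$fs, filter_spec$fs))) {
      gse_stop(sprintf("epoch fs (%g) != filter fs (%g)",
                       es$fs, filter_spec$fs), "gse_param_error")
    }
    flt <- design_bandpass(filter_spec)
    X <- .sos_filtfilt_mat(flt$sos, X, .gse_pad(d[3L]))
  }
  se <- .se_matrix(X, es$fs, band)
  if (anyNA(se)) {
    i <- which(is.na(se))[1L] - 1L
    gse_stop(sprintf(
      "all-zero in-band power at epoch %d, channel %d",
      i %/% d[2L] + 1L, i %% d[2L] + 1L
    ), "gse_degenerate_error")
  }
  values <- matrix(se, nrow = d[1L], ncol = d[2L], byrow = TRUE)
  feature_matrix(values, labels = es$labels,
                 channel_names = es$channel_names, band = band)
}
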