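# Shared fixture builders. Everything is generated in code; no binary data.

# Small labelled epoch set with reproducible random content.
make_epochs <- function(n_epochs = 4, n_channels = 3, n_samples = 64,
                        fs = 64, seed = 1,
                        labels = rep(c("alcoholic", "control"),
                                     length.out = n_epochs)) {
  gammaSE:::with_local_seed(seed, {
    epoch_set(
      array(stats::rnorm(n_epochs * n_channels * n_samples),
            dim = c(n_epochs, n_channels, n_samples)),
      labels = labels, fs = fs
    )
  })
}

# Epoch set where every trace is the same deterministic tone mixture.
make_tone_epochs <- function(freqs_hz, amps = rep(1, length(freqs_hz)),
                             n_epochs = 1, n_channels = 1, fs = 256,
                             n_samples = 256,
                             labels = rep("control", n_epochs)) {
  t_s <- (seq_len(n_samples) - 1) / fs
  trace <- colSums(amps * t(sapply(freqs_hz, function(f) sin(2 * pi * f * t_s))))
  if (length(freqs_hz) == 1) trace <- amps * sin(2 * pi * freqs_hz * t_s)
  data <- array(rep(trace, each = n_epochs * n_channels),
                dim = c(n_epochs, n_channels, n_samples))
  epoch_set(data, labels = labels, fs = fs)
}

# Write a tiny trial file in the public four-column layout and return its
# path. `rows` is a data frame with trial, channel, sample, value.
write_uci_fixture <- function(rows, header = "# co2c0000001.rd") {
  path <- tempfile(fileext = ".rd")
  lines <- c(header,
             "# 4 chan, trial 0",
             apply(rows, 1, paste, collapse = " "))
  writeLines(lines, path)
  path
}

uci_rows_2ch4s <- function() {
  data.frame(
    trial = 0L,
    channel = rep(c("A", "B"), each = 4),
    sample = rep(0:3, times = 2),
    value = 0:7
  )
}

# Feature matrix with prescribed per-channel group means (values stay in
# [0, 1]); channel k has mean gap `gaps[k]` between alcoholic and control.
make_gap_features <- function(n_per_group, gaps, sd = 0.02, seed = 1,
                              base = 0.5) {
  gammaSE:::with_local_seed(seed, {
    C <- length(gaps)
    alc <- matrix(stats::rnorm(n_per_group * C, base, sd), n_per_group, C)
    ctl <- matrix(stats::rnorm(n_per_group * C, base, sd), n_per_group, C)
    alc <- sweep(alc, 2, gaps, `+`)
    v <- pmin(pmax(rbind(alc, ctl), 0), 1)
    feature_matrix(v, labels = rep(c("alcoholic", "control"),
                                   each = n_per_group))
  })
}
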