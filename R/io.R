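# On-disk formats: public trial-file reader, epoch store, feature tables.
# All formats are plain text; numeric values are written with 17 significant
# digits so that write -> read round-trips are bit-exact.

.GSE_NUM_FMT <- "%.17g"

#' Read one trial of the public alcoholism EEG text format
#'
#' Parses a single-trial file in the whitespace-delimited layout used by the
#' public alcoholism EEG database: lines starting with `#` are comments, and
#' every data row has four fields, `trial_index channel_name sample_index
#' value`, with 0-based sample indices and values in microvolts. Channel
#' order follows first appearance in the file.
#'
#' @param path path to the trial file.
#' @param fs sampling rate in Hz (the public recordings use 256 Hz).
#' @param duration_s epoch duration in seconds; together with `fs` this
#'   declares the expected sample range `0 .. round(fs * duration_s) - 1`.
#' @param label group label for the trial. When `NULL`, the reader tries to
#'   infer it from the comment header (subject identifiers of the form
#'   `co2a...` / `co2c...`, where `a` marks an alcoholic and `c` a control
#'   subject); if inference fails an error asks for an explicit label.
#'
#' @return A one-epoch [epoch_set].
#' @export
read_uci_trial <- function(path, fs = 256, duration_s = 1, label = NULL) {
  if (!file.exists(path)) {
    gse_stop(sprintf("file not found: %s", path), "gse_io_error")
  }
  n_samples <- round(fs * duration_s)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  data_idx <- which(!is_comment & !is_blank)
  if (length(data_idx) == 0L) {
    gse_stop(sprintf("no data rows in %s (incomplete channel data)", path),
             "gse_incomplete_error")
  }

  toks <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- lengths(toks)
  if (any(nf != 4L)) {
    bad <- data_idx[which(nf != 4L)[1L]]
    gse_stop(sprintf("malformed row at line %d of %s: expected 4 fields, got %d",
                     bad, path, nf[which(nf != 4L)[1L]]),
             "gse_parse_error")
  }
  mat <- do.call(rbind, toks)
  chan <- mat[, 2L]
  smp <- suppressWarnings(as.integer(mat[, 3L]))
  val <- suppressWarnings(as.numeric(mat[, 4L]))
  if (anyNA(smp)) {
    bad <- data_idx[which(is.na(smp))[1L]]
    gse_stop(sprintf("malformed sample index at line %d of %s", bad, path),
             "gse_parse_error")
  }
  if (anyNA(val)) {
    bad <- data_idx[which(is.na(val))[1L]]
    gse_stop(sprintf("malformed value at line %d of %s", bad, path),
             "gse_parse_error")
  }
  out_of_range <- smp < 0L | smp >= n_samples
  if (any(out_of_range)) {
    i <- which(out_of_range)[1L]
    gse_stop(sprintf(
      "sample index %d out of declared range [0, %d] at line %d of %s",
      smp[i], n_samples - 1L, data_idx[i], path
    ), "gse_parse_error")
  }

  channel_names <- unique(chan)
  key <- paste(chan, smp)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    gse_stop(sprintf(
      "duplicate sample: channel %s, sample index %d (line %d of %s)",
      chan[i], smp[i], data_idx[i], path
    ), "gse_duplicate_error")
  }
  counts <- table(factor(chan, levels = channel_names))
  if (any(counts != n_samples)) {
    short <- names(counts)[counts != n_samples][1L]
    gse_stop(sprintf(
      "incomplete channel %s in %s: %d of %d samples present",
      short, path, counts[[short]], n_samples
    ), "gse_incomplete_error")
  }

  if (is.null(label)) {
    label <- .infer_uci_label(lines[is_comment])
    if (is.null(label)) {
      gse_stop(paste0(
        "cannot infer group label from the file header of ", path,
        "; pass `label = \"alcoholic\"` or `label = \"control\"` explicitly"
      ), "gse_param_error")
    }
  }

  data <- array(0, dim = c(1L, length(channel_names), n_samples))
  ci <- match(chan, channel_names)
  data[cbind(1L, ci, smp + 1L)] <- val
  epoch_set(data, labels = label, fs = fs,
            channel_names = channel_names, duration_s = duration_s)
}

# Subject ids in the public database look like "co2a0000364" (alcoholic) or
# "co2c0000337" (control); accept the spelled-out words too.
.infer_uci_label <- function(comment_lines) {
  txt <- paste(comment_lines, collapse = " ")
  if (grepl("alcoholic", txt, ignore.case = TRUE)) return("alcoholic")
  if (grepl("control", txt, ignore.case = TRUE)) return("control")
  m <- regmatches(txt, regexpr("co[0-9]*[ac][0-9]+", txt))
  if (length(m) == 1L) {
    code <- sub("^co[0-9]*", "", m)
    return(if (substr(code, 1L, 1L) == "a") "alcoholic" else "control")
  }
  NULL
}

#' Write and read epoch sets as self-describing text
#'
#' `write_epochs()` stores an [epoch_set] in a plain-text container: a
#' commented header with the sampling metadata, channel names and labels,
#' followed by one row per (epoch, channel) holding the full sample trace.
#' Values are written with 17 significant digits, so
#' `read_epochs(write_epochs(es))` reproduces `es` exactly.
#'
#' @param es an [epoch_set]; it is re-validated before writing, so objects
#'   with broken invariants (e.g. duplicate channel names) are refused.
#' @param path destination / source file path.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` an
#'   [epoch_set].
#' @export
write_epochs <- function(es, path) {
  validate_epoch_set(es)
  if (any(grepl("\t", es$channel_names))) {
    gse_stop("channel names must not contain tab characters",
             "gse_param_error")
  }
  d <- dim(es$data)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) gse_stop(
                    sprintf("cannot open %s for writing: %s",
                            path, conditionMessage(e)), "gse_io_error"))
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "# gammaSE-epochs v1",
    sprintf("# fs\t%s", sprintf(.GSE_NUM_FMT, es$fs)),
    sprintf("# duration_s\t%s", sprintf(.GSE_NUM_FMT, es$duration_s)),
    sprintf("# n_epochs\t%d", d[1L]),
    sprintf("# n_channels\t%d", d[2L]),
    sprintf("# n_samples\t%d", d[3L]),
    paste0("# channels\t", paste(es$channel_names, collapse = "\t")),
    paste0("# labels\t", paste(es$labels, collapse = "\t"))
  ), con)
  if (d[1L] > 0L) {
    for (e in seq_len(d[1L])) {
      rows <- vapply(seq_len(d[2L]), function(ch) {
        paste(c(e, ch, sprintf(.GSE_NUM_FMT, es$data[e, ch, ])),
              collapse = "\t")
      }, character(1L))
      writeLines(rows, con)
    }
  }
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) {
    gse_stop(sprintf("file not found: %s", path), "gse_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1L] != "# gammaSE-epochs v1") {
    gse_stop(sprintf("%s is not a gammaSE epochs file", path),
             "gse_parse_error")
  }
  hdr <- lines[startsWith(lines, "# ")]
  get_field <- function(key) {
    row <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    if (length(row) != 1L) {
      gse_stop(sprintf("missing header field '%s' in %s", key, path),
               "gse_parse_error")
    }
    strsplit(sub(paste0("^# ", key, "\t"), "", row), "\t")[[1L]]
  }
  fs <- as.numeric(get_field("fs"))
  duration_s <- as.numeric(get_field("duration_s"))
  n_epochs <- as.integer(get_field("n_epochs"))
  n_channels <- as.integer(get_field("n_channels"))
  n_samples <- as.integer(get_field("n_samples"))
  channel_names <- get_field("channels")
  labels <- if (n_epochs > 0L) get_field("labels") else character(0L)

  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(data_lines) != n_epochs * n_channels) {
    gse_stop(sprintf(
      "expected %d data rows in %s, found %d",
      n_epochs * n_channels, path, length(data_lines)
    ), "gse_parse_error")
  }
  data <- array(0, dim = c(n_epochs, n_channels, n_samples))
  if (n_epochs > 0L) {
    for (row in data_lines) {
      f <- strsplit(row, "\t", fixed = TRUE)[[1L]]
      if (length(f) != n_samples + 2L) {
        gse_stop(sprintf("malformed data row in %s", path), "gse_parse_error")
      }
      e <- as.integer(f[1L]); ch <- as.integer(f[2L])
      data[e, ch, ] <- as.numeric(f[-(1:2)])
    }
  }
  epoch_set(data, labels = labels, fs = fs,
            channel_names = channel_names, duration_s = duration_s)
}

#' Write and read feature matrices as CSV
#'
#' Delimited-text persistence for a [feature_matrix]: a `# band f1 f2`
#' comment line, then a header row (`label` plus the channel names) and one
#' row per epoch. Channel names are preserved exactly. Reading validates the
#' label column and rejects rows with missing cells.
#'
#' @param fm a [feature_matrix].
#' @param path destination / source file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a [feature_matrix].
#' @export
write_features <- function(fm, path) {
  validate_feature_matrix(fm)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) gse_stop(
                    sprintf("cannot open %s for writing: %s",
                            path, conditionMessage(e)), "gse_io_error"))
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# band %s %s",
                     sprintf(.GSE_NUM_FMT, fm$band[1L]),
                     sprintf(.GSE_NUM_FMT, fm$band[2L])), con)
  header <- paste(c("label", fm$channel_names), collapse = ",")
  writeLines(header, con)
  if (nrow(fm$values) > 0L) {
    body <- vapply(seq_len(nrow(fm$values)), function(i) {
      paste(c(fm$labels[i], sprintf(.GSE_NUM_FMT, fm$values[i, ])),
            collapse = ",")
    }, character(1L))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    gse_stop(sprintf("file not found: %s", path), "gse_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1L], "# band ")) {
    gse_stop(sprintf("%s is not a gammaSE feature CSV", path),
             "gse_parse_error")
  }
  band <- as.numeric(strsplit(sub("^# band ", "", lines[1L]), " ")[[1L]])
  header <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "label") {
    gse_stop(sprintf("first column of %s must be 'label'", path),
             "gse_parse_error")
  }
  channel_names <- header[-1L]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  n <- length(body)
  values <- matrix(NA_real_, n, length(channel_names))
  labels <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    if (length(f) != length(channel_names) + 1L || any(!nzchar(f))) {
      gse_stop(sprintf("missing cell at data row %d of %s", i, path),
               "gse_parse_error")
    }
    labels[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) {
      gse_stop(sprintf("non-numeric cell at data row %d of %s", i, path),
               "gse_parse_error")
    }
    values[i, ] <- v
  }
  check_labels(labels, error_class = "gse_parse_error")
  feature_matrix(values, labels = labels, channel_names = channel_names,
                 band = band)
}
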