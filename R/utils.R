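# Internal helpers shared across modules.

# Group labels used throughout; "alcoholic" is the positive class.
GSE_GROUPS <- c("alcoholic", "control")

# Signal a classed condition so callers (and tests) can match on error type.
# Every condition also carries the umbrella class "gse_error".
gse_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "gse_error", "error"), call = call))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps every seeded operation in the package
# reproducible without clobbering the user's RNG.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    gse_stop("`seed` must be a single non-missing number", "gse_param_error")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Validate a vector of group labels.
check_labels <- function(labels, error_class = "gse_param_error") {
  labels <- as.character(labels)
  bad <- !(labels %in% GSE_GROUPS)
  if (any(bad)) {
    gse_stop(
      sprintf(
        "labels must be one of {%s}; found: %s",
        paste(GSE_GROUPS, collapse = ", "),
        paste(unique(labels[bad]), collapse = ", ")
      ),
      error_class
    )
  }
  labels
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x >= 0
}
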