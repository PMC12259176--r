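## Internal helpers shared across modules: seeded sub-streams, spike-count
## windows, and small argument checks.

# Derive a deterministic 31-bit sub-seed from a root seed and a stream name, so
# that all randomness flows from one root seed via named sub-streams (images,
# sequence, units, spikes, behavior, folds, ...).
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h + 1) %% 2147483647)
}

# Run code under a fixed seed if one is supplied, otherwise under the current
# RNG state.
with_stream <- function(seed, stream, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(derive_seed(seed, stream), code)
}

check_window <- function(window, bin_edges) {
  if (length(window) != 2L || !is.numeric(window) || window[2] <= window[1]) {
    abort("`window` must be a numeric [start, end] pair in ms with end > start.")
  }
  if (window[1] < bin_edges[1] || window[2] > bin_edges[length(bin_edges)]) {
    abort(sprintf(
      "window [%g, %g] ms falls outside recorded bins [%g, %g] ms.",
      window[1], window[2], bin_edges[1], bin_edges[length(bin_edges)]
    ))
  }
  invisible(window)
}

# Indices of bins fully or partially inside [window[1], window[2]), plus the
# overlap (in ms) of each selected bin with the window.
window_bins <- function(window, bin_edges) {
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  ov <- pmin(hi, window[2]) - pmax(lo, window[1])
  keep <- which(ov > 1e-9)
  list(idx = keep, overlap_ms = ov[keep], duration_ms = window[2] - window[1])
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%null%` <- function(a, b) if (is.null(a)) b else a
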