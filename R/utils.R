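# Internal helpers shared across modules.

# Trapezoidal integral of y sampled at uniform spacing dt, over the samples
# i0..i1 (inclusive). Treats the samples as nodes, so the integrated width is
# (i1 - i0) * dt.
trapz_idx <- function(y, i0, i1, dt) {
  if (i1 <= i0) return(0)
  seg <- y[i0:i1]
  dt * (sum(seg) - (seg[1L] + seg[length(seg)]) / 2)
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Map a 1-based sample index on a source clock to the nearest 1-based index
# on a target clock; streams are assumed synchronized at t = 0.
map_index <- function(idx, fs_from, fs_to) {
  as.integer(round_half_up((idx - 1) * fs_to / fs_from)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Seeds are combined additively into 32-bit range for named substreams.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}
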