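#' Detect gait events from the insole force trace
#'
#' Foot-ground contacts are found by thresholding total plantar force at
#' `threshold_N` (default 50 N): heel strike is the first sample at or above
#' the threshold following a sub-threshold (swing) interval of at least
#' `min_off_s`, and toe-off is the first subsequent sample where force stays
#' below the threshold for at least `min_off_s`. Sub-threshold dips shorter
#' than `min_off_s` are treated as chatter and absorbed into the contact.
#' Leading and trailing partial contacts (those touching either end of the
#' trace without a qualifying swing interval) are discarded.
#'
#' @param force Total plantar force series, Newtons.
#' @param fs Sampling rate, Hz.
#' @param threshold_N Contact threshold in Newtons (default 50).
#' @param min_off_s Minimum sub-threshold duration (s) accepted as a swing
#'   interval (default 0.05).
#' @return A data.frame with columns `hs_idx` and `to_idx` (1-based sample
#'   indices; `to_idx` is the first sub-threshold sample after the contact).
#'   Zero rows when no complete contact is found.
#' @export
detect_gait_events <- function(force, fs, threshold_N = 50, min_off_s = 0.05) {
  if (length(force) == 0L) stopf("detect_gait_events: force must be non-empty")
  if (threshold_N <= 0) stopf("detect_gait_events: threshold_N must be > 0")
  min_off <- max(1L, as.integer(round(min_off_s * fs)))
  below <- force < threshold_N
  r <- rle(below)
  # absorb sub-threshold dips shorter than the debounce window, except at the
  # trace edges where they leave the adjacent contact partial
  n_runs <- length(r$lengths)
  if (n_runs > 2L) {
    interior <- 2:(n_runs - 1L)
    short <- interior[r$values[interior] & r$lengths[interior] < min_off]
    if (length(short)) {
      r$values[short] <- FALSE
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_runs <- length(r$lengths)
  events <- list()
  for (j in seq_len(n_runs)) {
    if (r$values[j]) next  # contact = above-threshold run
    if (j == 1L || j == n_runs) next  # partial: touches a trace edge
    if (r$lengths[j - 1L] < min_off || r$lengths[j + 1L] < min_off) next
    events[[length(events) + 1L]] <- c(hs_idx = starts[j],
                                       to_idx = ends[j] + 1L)
  }
  if (length(events) == 0L) {
    return(data.frame(hs_idx = integer(0), to_idx = integer(0)))
  }
  as.data.frame(do.call(rbind, events))
}

#' Segment detected contacts into gait cycles
#'
#' One stride per consecutive heel-strike pair, spanning the half-open
#' interval from one heel strike to the next; the last contact has no closing
#' heel strike and is dropped. Stance time is toe-off minus heel strike,
#' swing time is the next heel strike minus toe-off.
#'
#' @param events Data.frame from [detect_gait_events()].
#' @param fs Sampling rate, Hz.
#' @return A data.frame with one row per stride: `hs_idx`, `to_idx`,
#'   `next_hs_idx`, `stance_time_s`, `swing_time_s`. Zero rows when fewer
#'   than two heel strikes are available.
#' @export
segment_strides <- function(events, fs) {
  n <- nrow(events)
  if (is.null(n) || n < 2L) {
    return(data.frame(hs_idx = integer(0), to_idx = integer(0),
                      next_hs_idx = integer(0), stance_time_s = numeric(0),
                      swing_time_s = numeric(0)))
  }
  hs <- events$hs_idx[-n]
  to <- events$to_idx[-n]
  next_hs <- events$hs_idx[-1L]
  data.frame(hs_idx = hs, to_idx = to, next_hs_idx = next_hs,
             stance_time_s = (to - hs) / fs,
             swing_time_s = (next_hs - to) / fs)
}
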