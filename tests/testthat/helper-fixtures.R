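# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 4 subjects x 3 conditions x 4 speeds x 1 trial x 8 strides = 384 strides
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(sim_config(n_subjects = 4, trials_per_cell = 1,
                               strides_per_trial = 8, seed = 42))
  })
}

small_dataset <- function() {
  fixture("small_dataset", function() {
    build_dataset(small_cohort()$trials, locations = "boot", quiet = TRUE)
  })
}

cheap_config <- function(seed = 5L) {
  model_config(grid_length = 8, inner_cv_folds = 3, seed = seed)
}

# Independent ordinary-least-squares oracle (normal equations).
ols_coef <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  drop(solve(crossprod(xm), crossprod(xm, y)))
}

# Independent brute-force gait event oracle: explicit sample-by-sample scan.
# Contacts are maximal above-threshold runs after filling interior
# sub-threshold gaps shorter than the debounce window; a contact counts only
# when flanked on both sides by sub-threshold runs of at least that window,
# neither touching a trace edge.
scan_gait_events <- function(force, fs, threshold = 50, min_off_s = 0.05) {
  min_off <- max(1L, round(min_off_s * fs))
  n <- length(force)
  merged <- force >= threshold
  i <- 1L
  while (i <= n) {
    if (!merged[i]) {
      j <- i
      while (j <= n && !merged[j]) j <- j + 1L
      if (i > 1L && j <= n && (j - i) < min_off) merged[i:(j - 1L)] <- TRUE
      i <- j
    } else {
      i <- i + 1L
    }
  }
  events <- list()
  i <- 1L
  while (i <= n) {
    if (merged[i]) {
      j <- i
      while (j <= n && merged[j]) j <- j + 1L
      prev_len <- 0L
      k <- i - 1L
      while (k >= 1L && !merged[k]) {
        prev_len <- prev_len + 1L
        k <- k - 1L
      }
      next_len <- 0L
      k <- j
      while (k <= n && !merged[k]) {
        next_len <- next_len + 1L
        k <- k + 1L
      }
      if (i > 1L && j <= n && prev_len >= min_off && next_len >= min_off) {
        events[[length(events) + 1L]] <- c(i, j)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(events)) {
    return(data.frame(hs_idx = integer(0), to_idx = integer(0)))
  }
  m <- do.call(rbind, events)
  data.frame(hs_idx = m[, 1L], to_idx = m[, 2L])
}

# A synthetic insole trace of clean rectangular contacts, with known events.
rect_force <- function(contacts, total_n, high = 400) {
  force <- numeric(total_n)
  for (c_ in contacts) force[c_[1L]:c_[2L]] <- high
  force
}
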