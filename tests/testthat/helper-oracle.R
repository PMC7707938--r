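# Independent brute-force oracle for permutation entropy: explicit loops,
# selection-sort-based pattern extraction, and list-based tallying. Kept
# deliberately naive and separate from the package's vectorised path.

oracle_pattern <- function(w) {
  m <- length(w)
  idx <- seq_len(m)
  # selection sort on (value, original index)
  for (i in seq_len(m - 1L)) {
    best <- i
    for (j in (i + 1L):m) {
      if (w[idx[j]] < w[idx[best]] ||
          (w[idx[j]] == w[idx[best]] && idx[j] < idx[best])) {
        best <- j
      }
    }
    tmp <- idx[i]; idx[i] <- idx[best]; idx[best] <- tmp
  }
  idx
}

oracle_entropy <- function(x, m, tau, weighted = FALSE, normalized = FALSE) {
  n <- length(x)
  k <- n - (m - 1L) * tau
  tally <- list()
  for (i in seq_len(k)) {
    w <- x[i + (0:(m - 1L)) * tau]
    key <- paste(oracle_pattern(w), collapse = "-")
    wt <- if (weighted) sum((w - sum(w) / m)^2) / m else 1
    tally[[key]] <- (tally[[key]] %||% 0) + wt
  }
  tot <- sum(unlist(tally))
  if (tot <= 0) return(0)
  h <- 0
  for (v in unlist(tally)) {
    p <- v / tot
    if (p > 0) h <- h - p * log(p)
  }
  if (normalized) h / log(factorial(m)) else h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic band-limited test tone
tone <- function(freq, fs = 1000, n = 3000) sin(2 * pi * freq * (0:(n - 1)) / fs)

# Small fast generator configuration for structural tests
small_config <- function(seed = 1, reps = 2, duration = 0.6) {
  generator_config(reps_per_class = reps, duration = duration, seed = seed)
}
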