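# Ordinal-pattern primitives: Bandt-Pompe symbolisation, permutation entropy
# (PE) and variance-weighted permutation entropy (WPE), all in nats.

#' Embedding parameters for ordinal-pattern analysis
#'
#' Bundles and validates the time-delay embedding parameters used by all
#' entropy functions in the package. Defaults follow the common choice for
#' surface-EMG analysis: embedding dimension `m = 4`, delay `tau = 1`.
#'
#' @param m Embedding dimension (window length). At least 2; capped at
#'   `max_m` so that the `factorial(m)` ordinal patterns stay enumerable.
#' @param tau Embedding delay in samples (positive integer).
#' @param normalized If `TRUE`, entropies are divided by `log(factorial(m))`
#'   so they lie in `[0, 1]`; otherwise they are reported in nats.
#' @param max_m Upper cap on `m` (default 8). Raising it is possible but
#'   `factorial(m)` grows quickly; the default keeps pattern tables small.
#' @return An object of class `embedding_config`.
#' @examples
#' embedding_config()          # m = 4, tau = 1
#' embedding_config(m = 3, tau = 2)
#' @export
embedding_config <- function(m = 4L, tau = 1L, normalized = FALSE, max_m = 8L) {
  m <- as.integer(m)
  tau <- as.integer(tau)
  if (is.na(m) || m < 2L) stop_wwpe("embedding dimension `m` must be an integer >= 2")
  if (m > max_m) {
    stop_wwpe("embedding dimension m = %d exceeds the cap of %d (factorial(m) must stay enumerable); raise `max_m` explicitly if you really want this", m, max_m)
  }
  if (is.na(tau) || tau < 1L) stop_wwpe("delay `tau` must be an integer >= 1")
  structure(
    list(m = m, tau = tau, normalized = isTRUE(normalized)),
    class = "embedding_config"
  )
}

as_embedding_config <- function(cfg) {
  if (inherits(cfg, "embedding_config")) return(cfg)
  stop_wwpe("expected an `embedding_config` object; see embedding_config()")
}

#' @export
print.embedding_config <- function(x, ...) {
  cat(sprintf("embedding_config: m = %d, tau = %d, %s\n",
              x$m, x$tau,
              if (x$normalized) "normalized (/ log m!)" else "nats"))
  invisible(x)
}

#' Time-delay embedding of a scalar series
#'
#' Builds the matrix of delay vectors `(x[i], x[i + tau], ...,
#' x[i + (m-1) tau])` for `i = 1, ..., N - (m-1) tau`, one window per row.
#'
#' @param x Numeric vector (the signal), all values finite.
#' @param cfg An [embedding_config()].
#' @return A numeric matrix with `N - (m-1)*tau` rows and `m` columns.
#' @examples
#' embed_series(1:5, embedding_config(m = 3, tau = 1))
#' @export
embed_series <- function(x, cfg = embedding_config()) {
  cfg <- as_embedding_config(cfg)
  x <- check_numeric_vector(x, "x", min_len = 2L)
  n <- length(x)
  k <- n - (cfg$m - 1L) * cfg$tau
  if (k < 1L) {
    stop_wwpe("signal of length %d is too short for m = %d, tau = %d (need at least %d samples)",
              n, cfg$m, cfg$tau, (cfg$m - 1L) * cfg$tau + 1L)
  }
  W <- matrix(0, nrow = k, ncol = cfg$m)
  for (j in seq_len(cfg$m)) {
    start <- (j - 1L) * cfg$tau + 1L
    W[, j] <- x[start:(start + k - 1L)]
  }
  W
}

#' Ordinal pattern of a single window
#'
#' Returns the positions of the window's values sorted in ascending order.
#' Ties are broken by original position (a stable ascending sort), so equal
#' values keep their within-window order; tie-breaking is never random.
#'
#' @param window Numeric vector of finite values (one embedding window).
#' @return Integer vector: a permutation of `1:length(window)`.
#' @examples
#' ordinal_pattern(c(9, 10, 6))  # -> 3 1 2
#' ordinal_pattern(c(5, 5, 5))   # -> 1 2 3 (ties keep index order)
#' @export
ordinal_pattern <- function(window) {
  window <- check_numeric_vector(window, "window", min_len = 2L)
  order(window, seq_along(window), method = "radix")
}

# Integer code of each window's ordinal pattern, vectorised over rows of W.
# Rank of column j = 1 + #{l : x_l < x_j, or x_l == x_j and l < j}; the rank
# vector is the inverse of the pattern permutation and codes bijectively.
pattern_codes <- function(W) {
  m <- ncol(W)
  k <- nrow(W)
  r <- matrix(1L, nrow = k, ncol = m)
  for (j in 2:m) {
    for (l in 1:(j - 1L)) {
      le <- W[, l] <= W[, j]  # tie -> earlier index ranks lower
      r[, j] <- r[, j] + le
      r[, l] <- r[, l] + !le
    }
  }
  drop((r - 1L) %*% m^(0:(m - 1L)))
}

# Decode an integer pattern code back to the ordinal pattern (j1, ..., jm).
decode_pattern <- function(code, m) {
  ranks <- integer(m)
  for (j in seq_len(m)) {
    ranks[j] <- code %% m + 1L
    code <- code %/% m
  }
  order(ranks)
}

pattern_label <- function(indices) paste(indices, collapse = "-")

# Population variance of each window (divide by m), zero iff constant.
window_weights <- function(W) {
  mu <- rowMeans(W)
  rowMeans((W - mu)^2)
}

#' Amplitude weight of one embedding window
#'
#' The weight is the population variance of the window values (sum of squared
#' deviations from the window mean divided by `m`, not `m - 1`). Constant
#' windows get weight zero.
#'
#' @param window Numeric vector of finite values.
#' @return A single non-negative number.
#' @examples
#' window_weight(c(10, 6, 11))  # 14/3
#' @export
window_weight <- function(window) {
  window <- check_numeric_vector(window, "window", min_len = 1L)
  mean((window - mean(window))^2)
}

#' Ordinal-pattern distribution of a signal
#'
#' Tabulates the ordinal patterns of all embedding windows of `x`. With
#' `weighted = FALSE` each window counts 1 (plain relative frequencies);
#' with `weighted = TRUE` each window contributes its amplitude
#' [window_weight()], and the per-pattern totals are normalised by the total
#' weight. A signal whose every window is constant has total weight zero: the
#' weighted distribution is then flagged degenerate (all probabilities zero).
#'
#' @param x Numeric signal vector.
#' @param cfg An [embedding_config()].
#' @param weighted Use variance weights instead of plain counts?
#' @return An object of class `pattern_distribution`: a list with `probs`
#'   (named numeric vector, names like `"3-1-2"`), `patterns` (list of
#'   integer permutations), `kind` (`"plain"` or `"weighted"`),
#'   `support_count`, `n_windows`, `m`, and `degenerate`.
#' @examples
#' pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), embedding_config(m = 3))
#' @export
pattern_distribution <- function(x, cfg = embedding_config(), weighted = FALSE) {
  cfg <- as_embedding_config(cfg)
  W <- embed_series(x, cfg)
  codes <- pattern_codes(W)
  w <- if (weighted) window_weights(W) else rep(1, nrow(W))
  tot <- rowsum(w, codes)             # per-pattern totals, sorted by code
  ucodes <- as.numeric(rownames(tot))
  total <- sum(tot)
  degenerate <- total <= 0
  probs <- if (degenerate) rep(0, length(ucodes)) else drop(tot) / total
  patterns <- lapply(ucodes, decode_pattern, m = cfg$m)
  names(probs) <- vapply(patterns, pattern_label, character(1))
  if (degenerate) {
    warning("all embedding windows are constant: total weight is zero, weighted pattern distribution is degenerate", call. = FALSE)
  }
  structure(
    list(probs = probs, patterns = patterns,
         kind = if (weighted) "weighted" else "plain",
         support_count = sum(probs > 0),
         n_windows = nrow(W), m = cfg$m, degenerate = degenerate),
    class = "pattern_distribution"
  )
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("%s ordinal-pattern distribution (m = %d, %d windows, support %d/%d)\n",
              x$kind, x$m, x$n_windows, x$support_count, factorial(x$m)))
  print(round(x$probs, 4))
  invisible(x)
}

entropy_of <- function(probs, m, normalized) {
  p <- probs[probs > 0]
  if (length(p) == 0) return(0)       # degenerate distribution: zero complexity
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(m)) else h
}

#' Permutation entropy
#'
#' Shannon entropy (in nats) of the ordinal-pattern distribution of `x`:
#' `H = -sum(p * log(p))` over the patterns with non-zero probability.
#' Ranges from 0 (monotone signal, single pattern) to `log(factorial(m))`
#' (all patterns equally likely); the normalized variant divides by
#' `log(factorial(m))`.
#'
#' @inheritParams pattern_distribution
#' @return A single non-negative number.
#' @examples
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), embedding_config(m = 3))
#' @export
permutation_entropy <- function(x, cfg = embedding_config()) {
  cfg <- as_embedding_config(cfg)
  d <- pattern_distribution(x, cfg, weighted = FALSE)
  entropy_of(d$probs, cfg$m, cfg$normalized)
}

#' Weighted permutation entropy
#'
#' Like [permutation_entropy()], but each embedding window contributes its
#' population variance rather than a unit count, so the measure retains
#' amplitude information: high-variance excursions dominate the pattern
#' statistics. A constant signal (total weight zero) returns 0 by convention,
#' with a warning, since a constant signal has no complexity.
#'
#' @inheritParams pattern_distribution
#' @return A single non-negative number (nats, or in `[0, 1]` if
#'   `cfg$normalized`).
#' @examples
#' weighted_permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), embedding_config(m = 3))
#' @export
weighted_permutation_entropy <- function(x, cfg = embedding_config()) {
  cfg <- as_embedding_config(cfg)
  d <- pattern_distribution(x, cfg, weighted = TRUE)
  entropy_of(d$probs, cfg$m, cfg$normalized)
}
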