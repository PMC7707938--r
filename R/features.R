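# Trial container and feature extraction: WWPE, wavelet-PE, single sub-band
# entropies, undecomposed entropies, and the classical time-domain baseline.

#' A single multi-channel sEMG trial
#'
#' @param data Numeric channels x samples matrix (one row per electrode
#'   channel). A plain vector is treated as a single channel.
#' @param fs Sampling rate in Hz.
#' @param label Movement class of the trial (character), e.g. `"open"`.
#' @param subject_id,repetition Optional provenance tags.
#' @return Object of class `emg_trial`.
#' @examples
#' tr <- emg_trial(matrix(rnorm(4 * 512), nrow = 4), fs = 1000, label = "open")
#' tr
#' @export
emg_trial <- function(data, fs, label = NA_character_, subject_id = NA_character_,
                      repetition = NA_integer_) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data) || nrow(data) < 1L || ncol(data) < 2L) {
    stop_wwpe("`data` must be a numeric channels x samples matrix")
  }
  if (!all(is.finite(data))) stop_wwpe("trial data contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop_wwpe("`fs` must be a positive sampling rate in Hz")
  if (is.null(rownames(data))) rownames(data) <- paste0("ch", seq_len(nrow(data)))
  structure(
    list(data = data, fs = fs, label = as.character(label),
         subject_id = as.character(subject_id), repetition = as.integer(repetition)),
    class = "emg_trial"
  )
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("emg_trial: %d channels x %d samples @ %g Hz, label = %s\n",
              nrow(x$data), ncol(x$data), x$fs, x$label))
  invisible(x)
}

n_channels <- function(trial) nrow(trial$data)

#' Feature-set specification
#'
#' Describes one of the feature families the package can extract from a
#' trial. `"wwpe"` is the headline set: weighted permutation entropy of every
#' wavelet sub-band of every channel (4 channels x 5 sub-bands = 20
#' features at the defaults). `"wavelet_pe"` is its unweighted counterpart;
#' `"subband_wpe"`/`"subband_pe"` use a single named sub-band (one feature
#' per channel); `"raw_wpe"`/`"raw_pe"` skip the decomposition entirely;
#' `"time_domain"` is the classical RMS/MAV/WL/ZC/SSC baseline.
#'
#' @param kind One of `"wwpe"`, `"wavelet_pe"`, `"subband_wpe"`,
#'   `"subband_pe"`, `"raw_wpe"`, `"raw_pe"`, `"time_domain"`.
#' @param band Sub-band label; required iff `kind` is `"subband_wpe"` or
#'   `"subband_pe"`.
#' @param embedding An [embedding_config()].
#' @param wavelet A [wavelet_config()].
#' @param zc_threshold,ssc_threshold Amplitude thresholds for the zero
#'   crossing and slope-sign-change counts of the time-domain set.
#' @return Object of class `feature_spec`.
#' @examples
#' feature_spec("wwpe")
#' feature_spec("subband_wpe", band = "d3")
#' @export
feature_spec <- function(kind = c("wwpe", "wavelet_pe", "subband_wpe", "subband_pe",
                                  "raw_wpe", "raw_pe", "time_domain"),
                         band = NULL,
                         embedding = embedding_config(),
                         wavelet = wavelet_config(),
                         zc_threshold = 0, ssc_threshold = 0) {
  kind <- match.arg(kind)
  needs_band <- kind %in% c("subband_wpe", "subband_pe")
  if (needs_band) {
    if (is.null(band)) stop_wwpe("feature kind \"%s\" requires a `band`", kind)
    labels <- subband_labels(wavelet$levels)
    if (!band %in% labels) {
      stop_wwpe("unknown band \"%s\"; valid bands: %s", band, paste(labels, collapse = ", "))
    }
  } else if (!is.null(band)) {
    stop_wwpe("`band` is only meaningful for subband_wpe / subband_pe")
  }
  structure(
    list(kind = kind, band = band, embedding = as_embedding_config(embedding),
         wavelet = wavelet, zc_threshold = zc_threshold, ssc_threshold = ssc_threshold),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("feature_spec: %s%s (m = %d, tau = %d, %s, %d levels)\n",
              x$kind, if (!is.null(x$band)) paste0("[", x$band, "]") else "",
              x$embedding$m, x$embedding$tau, x$wavelet$wavelet, x$wavelet$levels))
  invisible(x)
}

feature_spec_id <- function(spec) {
  if (is.null(spec$band)) spec$kind else paste(spec$kind, spec$band, sep = "_")
}

channel_names <- function(trial) rownames(trial$data)

#' WWPE feature vector of one trial
#'
#' For every channel: 4-level wavelet decomposition, reconstruction of the
#' five sub-band signals, and weighted permutation entropy of each. Features
#' are ordered channel-major with band order a4, d4, d3, d2, d1, giving
#' `channels x (levels + 1)` values (20 for a 4-channel trial at the
#' defaults).
#'
#' @param trial An [emg_trial()].
#' @param spec A [feature_spec()]; its `kind` selects weighted (`"wwpe"`)
#'   or plain (`"wavelet_pe"`) sub-band entropies.
#' @return Named numeric vector, names like `ch1_a4_wpe`.
#' @export
wwpe_features <- function(trial, spec = feature_spec("wwpe")) {
  weighted <- spec$kind != "wavelet_pe"
  tag <- if (weighted) "wpe" else "pe"
  labels <- subband_labels(spec$wavelet$levels)
  out <- numeric(0)
  for (ch in seq_len(n_channels(trial))) {
    x <- trial$data[ch, ]
    sb <- subband_set(x, spec$wavelet)
    v <- vapply(sb$bands[labels], band_entropy, numeric(1),
                scale = max(abs(x)), weighted = weighted, cfg = spec$embedding)
    names(v) <- paste(channel_names(trial)[ch], labels, tag, sep = "_")
    out <- c(out, v)
  }
  out
}

# Entropy of one reconstructed band, with a numerical-noise floor: the
# transform guarantees reconstruction only to 1e-8 of the input scale, so a
# band whose whole excursion lies below that is floating-point residue and
# counts as constant (zero complexity), not as a random signal.
band_entropy <- function(band, scale, weighted, cfg) {
  if (diff(range(band)) <= 1e-8 * max(scale, .Machine$double.eps)) {
    return(0)
  }
  if (weighted) weighted_permutation_entropy(band, cfg) else permutation_entropy(band, cfg)
}

#' Single-sub-band entropy features of one trial
#'
#' One (weighted) permutation entropy per channel, computed on the
#' reconstructed signal of a single wavelet sub-band; a 4-channel trial gives
#' a 4-dimensional vector.
#'
#' @param trial An [emg_trial()].
#' @param band Sub-band label (e.g. `"d3"`).
#' @param weighted Use weighted (`TRUE`) or plain permutation entropy.
#' @param embedding An [embedding_config()].
#' @param wavelet A [wavelet_config()].
#' @return Named numeric vector of length `n_channels(trial)`.
#' @export
subband_entropy_features <- function(trial, band, weighted = TRUE,
                                     embedding = embedding_config(),
                                     wavelet = wavelet_config()) {
  labels <- subband_labels(wavelet$levels)
  if (!band %in% labels) {
    stop_wwpe("unknown band \"%s\"; valid bands: %s", band, paste(labels, collapse = ", "))
  }
  tag <- if (weighted) "wpe" else "pe"
  n <- ncol(trial$data)
  v <- vapply(seq_len(n_channels(trial)), function(ch) {
    x <- trial$data[ch, ]
    coeffs <- wavelet_decompose(x, wavelet)
    band_entropy(reconstruct_subband(coeffs, band, n, wavelet),
                 scale = max(abs(x)), weighted = weighted, cfg = embedding)
  }, numeric(1))
  names(v) <- paste(channel_names(trial), band, tag, sep = "_")
  v
}

#' Entropy features of the undecomposed signal
#'
#' (Weighted) permutation entropy per channel on the raw, unfiltered signal.
#'
#' @inheritParams subband_entropy_features
#' @return Named numeric vector of length `n_channels(trial)`.
#' @export
raw_entropy_features <- function(trial, weighted = TRUE,
                                 embedding = embedding_config()) {
  ent <- if (weighted) weighted_permutation_entropy else permutation_entropy
  tag <- if (weighted) "wpe" else "pe"
  v <- vapply(seq_len(n_channels(trial)), function(ch) ent(trial$data[ch, ], embedding),
              numeric(1))
  names(v) <- paste(channel_names(trial), "raw", tag, sep = "_")
  v
}

# Classical Hudgins time-domain features of one channel.
time_domain_channel <- function(x, zc_threshold = 0, ssc_threshold = 0) {
  n <- length(x)
  if (n < 3L) stop_wwpe("time-domain features need at least 3 samples per channel")
  dx <- diff(x)
  zc <- sum(x[-n] * x[-1L] < 0 & abs(dx) >= zc_threshold)
  mid <- x[2:(n - 1L)]
  back <- mid - x[1:(n - 2L)]
  fwd <- mid - x[3:n]
  ssc <- sum(back * fwd > 0 & pmax(abs(back), abs(fwd)) >= ssc_threshold)
  c(rms = sqrt(mean(x^2)), mav = mean(abs(x)), wl = sum(abs(dx)),
    zc = zc, ssc = ssc)
}

#' Classical time-domain feature vector of one trial
#'
#' Per channel: root-mean-square (RMS), mean absolute value (MAV), waveform
#' length (WL, total variation), zero crossings (ZC, sign changes whose jump
#' exceeds `zc_threshold`) and slope sign changes (SSC, local extrema whose
#' sharper side exceeds `ssc_threshold`). Channel-major ordering; a
#' 4-channel trial gives 20 features.
#'
#' @param trial An [emg_trial()].
#' @param zc_threshold,ssc_threshold Non-negative amplitude thresholds
#'   (default 0); raise them to ignore noise-induced crossings.
#' @return Named numeric vector of length `5 * n_channels(trial)`.
#' @export
time_domain_features <- function(trial, zc_threshold = 0, ssc_threshold = 0) {
  out <- numeric(0)
  for (ch in seq_len(n_channels(trial))) {
    v <- time_domain_channel(trial$data[ch, ], zc_threshold, ssc_threshold)
    names(v) <- paste(channel_names(trial)[ch], names(v), sep = "_")
    out <- c(out, v)
  }
  out
}

extract_features <- function(trial, spec) {
  switch(spec$kind,
    wwpe = ,
    wavelet_pe = wwpe_features(trial, spec),
    subband_wpe = subband_entropy_features(trial, spec$band, TRUE, spec$embedding, spec$wavelet),
    subband_pe = subband_entropy_features(trial, spec$band, FALSE, spec$embedding, spec$wavelet),
    raw_wpe = raw_entropy_features(trial, TRUE, spec$embedding),
    raw_pe = raw_entropy_features(trial, FALSE, spec$embedding),
    time_domain = time_domain_features(trial, spec$zc_threshold, spec$ssc_threshold)
  )
}

#' Feature matrix of a labeled dataset
#'
#' Applies one [feature_spec()] to every trial of a dataset, producing a
#' trials x features matrix with a deterministic column order and the class
#' labels carried along. Trials must be homogeneous (same channel count and
#' sampling rate); any invalid trial aborts the build with its index in the
#' message.
#'
#' @param dataset An `emg_dataset` (see [generate_dataset()] or
#'   [read_manifest()]), or a plain list of [emg_trial()] objects.
#' @param spec A [feature_spec()].
#' @return Object of class `feature_matrix`: list with `values` (numeric
#'   matrix), `feature_names`, `labels` (factor), `spec_id`.
#' @examples
#' ds <- generate_dataset(generator_config(reps_per_class = 2, duration = 0.5, seed = 1))
#' fm <- build_feature_matrix(ds, feature_spec("subband_wpe", band = "d3"))
#' dim(fm$values)
#' @export
build_feature_matrix <- function(dataset, spec) {
  trials <- if (inherits(dataset, "emg_dataset")) dataset$trials else dataset
  if (length(trials) == 0L) stop_wwpe("dataset contains no trials")
  nch <- n_channels(trials[[1L]])
  fs <- trials[[1L]]$fs
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (!inherits(tr, "emg_trial")) stop_wwpe("trial %d is not an emg_trial", i)
    if (n_channels(tr) != nch || tr$fs != fs) {
      stop_wwpe("trial %d is heterogeneous (channels %d @ %g Hz vs %d @ %g Hz)",
                i, n_channels(tr), tr$fs, nch, fs)
    }
    rows[[i]] <- tryCatch(extract_features(tr, spec), error = function(e) {
      stop_wwpe("feature extraction failed on trial %d: %s", i, conditionMessage(e))
    })
  }
  values <- do.call(rbind, rows)
  labels <- factor(vapply(trials, function(tr) tr$label, character(1)))
  structure(
    list(values = values, feature_names = colnames(values), labels = labels,
         spec_id = feature_spec_id(spec)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d trials x %d features, %d classes\n",
              x$spec_id, nrow(x$values), ncol(x$values), nlevels(x$labels)))
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  data.frame(x$values, label = x$labels, check.names = FALSE)
}
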