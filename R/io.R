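# Readers and writers: one CSV per trial plus a JSON manifest, feature
# matrices and reports as CSV, and the end-to-end pipeline driver.

#' Read one trial from a delimiter-separated-value file
#'
#' Expects a rectangular numeric table, one column per channel, optionally
#' with a header row of channel names (auto-detected). Column order is the
#' channel order.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param label Class label to attach.
#' @param sep Field separator (default `","`).
#' @return An [emg_trial()].
#' @export
read_trial_dsv <- function(path, fs, label = NA_character_, sep = ",") {
  if (!file.exists(path)) stop_wwpe("trial file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop_wwpe("empty trial file: %s", path)
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- read.csv(path, header = has_header, sep = sep, check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 2L) stop_wwpe("trial file %s has no usable data", path)
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1L]
      stop_wwpe("non-numeric cell in %s, column %d, data line %d", path, j, bad)
    }
  }
  m <- t(as.matrix(df))
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop_wwpe("non-finite value in %s (channel %d, sample %d)", path, bad[1L], bad[2L])
  }
  if (!has_header) rownames(m) <- paste0("ch", seq_len(nrow(m)))
  emg_trial(m, fs = fs, label = label)
}

#' Write one trial as a delimiter-separated-value file
#'
#' One column per channel, header row of channel names, full-precision
#' floats (17 significant digits, enough for exact round-trip).
#'
#' @param trial An [emg_trial()].
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @export
write_trial_dsv <- function(trial, path, sep = ",") {
  df <- as.data.frame(t(trial$data))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = sep), con)
  body <- do.call(paste, c(lapply(df, format_full), list(sep = sep)))
  writeLines(body, con)
  invisible(path)
}

format_full <- function(x) sprintf("%.17g", x)

#' Write a dataset as per-trial files plus a manifest
#'
#' Each trial goes to `trial_<i>.csv`; `manifest.json` records the sampling
#' rate, class set, per-trial file/label/repetition and, for generated
#' datasets, the generator configuration, so the directory round-trips
#' through [read_manifest()].
#'
#' @param dataset An `emg_dataset` or list of [emg_trial()] objects.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest file, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  trials <- if (inherits(dataset, "emg_dataset")) dataset$trials else dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    fname <- sprintf("trial_%03d.csv", i)
    write_trial_dsv(trials[[i]], file.path(dir, fname))
    entries[[i]] <- list(file = fname, label = trials[[i]]$label,
                         repetition = trials[[i]]$repetition)
  }
  manifest <- list(
    fs = trials[[1L]]$fs,
    classes = sort(unique(vapply(trials, function(tr) tr$label, character(1)))),
    trials = entries
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset from a manifest
#'
#' Resolves the per-trial files relative to the manifest's directory and
#' checks homogeneity (all trials share the channel count and sampling
#' rate) and that every label belongs to the manifest's class set.
#'
#' @param path Path to a `manifest.json` written by [write_dataset()].
#' @return An `emg_dataset`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_wwpe("manifest not found: %s", path)
  manifest <- jsonlite::read_json(path)
  base <- dirname(path)
  if (length(manifest$trials) == 0L) stop_wwpe("manifest lists no trials")
  trials <- vector("list", length(manifest$trials))
  for (i in seq_along(manifest$trials)) {
    e <- manifest$trials[[i]]
    f <- file.path(base, e$file)
    if (!file.exists(f)) stop_wwpe("manifest references missing file: %s", e$file)
    if (!is.null(manifest$classes) && !(e$label %in% unlist(manifest$classes))) {
      stop_wwpe("trial %d label \"%s\" outside the manifest class set", i, e$label)
    }
    trials[[i]] <- read_trial_dsv(f, fs = manifest$fs, label = e$label)
    trials[[i]]$repetition <- as.integer(e$repetition %||% NA_integer_)
  }
  nch <- vapply(trials, n_channels, integer(1))
  if (length(unique(nch)) != 1L) stop_wwpe("trials have differing channel counts: %s",
                                           paste(unique(nch), collapse = ", "))
  structure(list(trials = trials, manifest = manifest), class = "emg_dataset")
}

#' Write a feature matrix as CSV
#'
#' Header row of feature names plus a final `label` column; full-precision
#' values.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param path Output file path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  cols <- c(lapply(df[seq_len(ncol(df) - 1L)], format_full),
            list(as.character(df$label)))
  writeLines(do.call(paste, c(cols, list(sep = ","))), con)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path File path.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% colnames(df)) stop_wwpe("feature matrix %s lacks a label column", path)
  values <- as.matrix(df[setdiff(colnames(df), "label")])
  structure(
    list(values = values, feature_names = colnames(values),
         labels = factor(df$label), spec_id = "file"),
    class = "feature_matrix"
  )
}

#' Configuration for an end-to-end run
#'
#' Collects every tunable of the pipeline with the package defaults:
#' embedding m = 4, tau = 1; sym8 wavelet, 4 levels; stratified 70/30
#' split; SVM and BPNN classifiers over 5 split seeds.
#'
#' @param feature_kinds Character vector of [feature_spec()] kinds to run;
#'   entries of the form `"subband_wpe:d3"` select a band.
#' @param m,tau,normalized Embedding parameters.
#' @param wavelet,levels Wavelet parameters.
#' @param train_fraction,seeds Split parameters.
#' @param classifiers Classifier kinds to run.
#' @param generator A [generator_config()] used when no dataset path is
#'   given.
#' @param dataset_path Optional manifest path of an on-disk dataset.
#' @param out_dir Where artifacts (feature matrices, report) are written;
#'   `NULL` keeps everything in memory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_kinds = c("wwpe", "raw_pe"),
                            m = 4L, tau = 1L, normalized = FALSE,
                            wavelet = "sym8", levels = 4L,
                            train_fraction = 0.7, seeds = 0:4,
                            classifiers = c("svm", "bpnn"),
                            generator = generator_config(),
                            dataset_path = NULL, out_dir = NULL) {
  emb <- embedding_config(m = m, tau = tau, normalized = normalized)
  wav <- wavelet_config(wavelet, levels)
  specs <- lapply(feature_kinds, function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1L]]
    feature_spec(parts[1L], band = if (length(parts) > 1L) parts[2L],
                 embedding = emb, wavelet = wav)
  })
  structure(
    list(specs = specs, embedding = emb, wavelet = wav,
         train_fraction = train_fraction, seeds = as.integer(seeds),
         classifiers = classifiers, generator = generator,
         dataset_path = dataset_path, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Decompose, extract, combine, classify: loads (or generates) a dataset,
#' builds every configured feature matrix, trains and evaluates every
#' configured classifier over the configured split seeds, and (optionally)
#' writes feature matrices and the comparison table to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The comparison data.frame from [compare_feature_sets()], with
#'   the dataset attached as attribute `"dataset"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dataset <- if (!is.null(config$dataset_path)) {
    read_manifest(config$dataset_path)
  } else {
    generate_dataset(config$generator)
  }
  results <- compare_feature_sets(dataset, config$specs,
                                  classifiers = config$classifiers,
                                  seeds = config$seeds,
                                  train_fraction = config$train_fraction)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (spec in config$specs) {
      fm <- build_feature_matrix(dataset, spec)
      write_feature_matrix(fm, file.path(config$out_dir,
                                         paste0("features_", fm$spec_id, ".csv")))
    }
    write.csv(results, file.path(config$out_dir, "report.csv"), row.names = FALSE)
  }
  attr(results, "dataset") <- dataset
  results
}
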