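# Shared end-to-end benchmark artifacts, built once per test run: the
# default 210-trial synthetic dataset and its WWPE feature matrix are used
# by both the separability and the permutation-null checks.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_dataset <- function() {
  if (is.null(.benchmark_cache$dataset)) {
    .benchmark_cache$dataset <- generate_dataset(generator_config(seed = 1))
  }
  .benchmark_cache$dataset
}

benchmark_wwpe <- function() {
  if (is.null(.benchmark_cache$wwpe)) {
    .benchmark_cache$wwpe <- build_feature_matrix(benchmark_dataset(),
                                                  feature_spec("wwpe"))
  }
  .benchmark_cache$wwpe
}

# mean accuracy of a feature matrix under SVM over the given split seeds
mean_svm_accuracy <- function(fm, seeds = 0:4, train_fraction = 0.7) {
  accs <- vapply(seeds, function(s) {
    sp <- stratified_split(fm$labels, train_fraction, s)
    clf <- train_svm(fm$values[sp$train, , drop = FALSE], fm$labels[sp$train])
    evaluate(clf, fm$values[sp$test, , drop = FALSE], fm$labels[sp$test])$average_accuracy
  }, numeric(1))
  mean(accs)
}
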