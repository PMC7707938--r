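# Classifiers and evaluation: stratified splitting, SVM (RBF) and a
# three-layer feed-forward network, per-movement and average accuracy, and
# the feature-set x classifier x seed comparison grid.

#' Stratified train/test split of a feature matrix
#'
#' Randomly assigns trials to train and test partitions, stratified by class
#' so the proportions hold within every movement. Reproducible: the split is
#' a pure function of `(labels, train_fraction, seed)`.
#'
#' @param labels Factor (or character) of class labels, one per trial.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7).
#' @param seed Integer seed controlling the assignment.
#' @return List with integer vectors `train` and `test` (disjoint,
#'   exhaustive row indices).
#' @examples
#' sp <- stratified_split(rep(c("a", "b"), each = 10), 0.7, seed = 1)
#' lengths(sp)
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 0L) {
  if (train_fraction <= 0 || train_fraction >= 1) stop_wwpe("`train_fraction` must be in (0, 1)")
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop_wwpe("every class needs >= 2 trials for a stratified split (smallest has %d)", min(counts))
  }
  rng <- local_rng(seed)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    k <- round(train_fraction * length(idx))
    k <- max(1L, min(length(idx) - 1L, k))  # both partitions keep every class
    train <- c(train, sample(idx, k))
  }
  rng()  # restore RNG state
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Seed the RNG locally; returns a restorer.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Column standardisation fitted on training data only.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  if (all(sdev == 0)) stop_wwpe("degenerate features: every column has zero variance on the training set")
  sdev[sdev == 0] <- 1  # constant columns pass through centred
  list(center = mu, scale = sdev)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

#' Train a support vector machine on a feature matrix
#'
#' RBF-kernel SVM (one-vs-one multiclass, via \pkg{e1071}) with features
#' standardised to training-set mean and SD inside the fitted pipeline, so
#' no test-set statistics leak into the transform.
#'
#' @param x Numeric trials x features matrix (training rows only).
#' @param y Class labels for the rows of `x` (>= 2 classes).
#' @param cost Soft-margin cost `C` (default 1).
#' @param gamma RBF kernel width; default `1 / ncol(x)`.
#' @return Object of class `emg_classifier`.
#' @export
train_svm <- function(x, y, cost = 1, gamma = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop_wwpe("training needs >= 2 classes")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  gamma <- gamma %||% (1 / ncol(x))
  fit <- e1071::svm(xs, y, kernel = "radial", cost = cost, gamma = gamma, scale = FALSE)
  structure(
    list(kind = "svm", fit = fit, scaler = scaler,
         feature_names = colnames(x), classes = levels(y)),
    class = "emg_classifier"
  )
}

#' Train a three-layer feed-forward network
#'
#' One hidden layer of logistic units with a softmax output
#' (back-propagation training via \pkg{nnet}); "three layers" counts input,
#' hidden and output. Weight initialisation is seeded, so a fixed seed gives
#' identical fits. Features are standardised with training-set statistics.
#'
#' @param x Numeric trials x features matrix (training rows only).
#' @param y Class labels (>= 2 classes).
#' @param hidden Hidden-layer size (default 20; must be >= 1).
#' @param maxit Maximum training epochs (default 500).
#' @param decay Weight decay (default 5e-4).
#' @param seed Seed for weight initialisation.
#' @return Object of class `emg_classifier`.
#' @export
train_bpnn <- function(x, y, hidden = 20L, maxit = 500L, decay = 5e-4, seed = 0L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop_wwpe("training needs >= 2 classes")
  if (hidden < 1L) stop_wwpe("`hidden` must be >= 1")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  restore <- local_rng(seed)
  fit <- nnet::nnet(xs, nnet::class.ind(y), size = hidden, softmax = TRUE,
                    maxit = maxit, decay = decay, trace = FALSE, MaxNWts = 10000L)
  restore()
  structure(
    list(kind = "bpnn", fit = fit, scaler = scaler,
         feature_names = colnames(x), classes = levels(y)),
    class = "emg_classifier"
  )
}

#' @export
print.emg_classifier <- function(x, ...) {
  cat(sprintf("emg_classifier: %s, %d features, classes: %s\n",
              x$kind, length(x$feature_names), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
predict.emg_classifier <- function(object, newdata, ...) {
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    stop_wwpe("feature columns do not match the training schema")
  }
  xs <- apply_scaler(newdata, object$scaler)
  if (object$kind == "svm") {
    requireNamespace("e1071", quietly = TRUE)  # registers predict.svm
    as.character(predict(object$fit, xs))
  } else {
    p <- predict(object$fit, xs)
    object$classes[max.col(p, ties.method = "first")]
  }
}

#' Evaluate a classifier on held-out trials
#'
#' @param classifier An `emg_classifier` from [train_svm()] or
#'   [train_bpnn()].
#' @param x Test trials x features matrix (same columns as training).
#' @param y True class labels of the test rows.
#' @return Object of class `evaluation_report`: confusion matrix (rows =
#'   truth), per-class accuracies (diagonal over row sum), and
#'   `average_accuracy` = overall fraction of correct predictions (equal to
#'   the macro average under balanced classes).
#' @export
evaluate <- function(classifier, x, y) {
  pred <- predict(classifier, x)
  y <- factor(as.character(y), levels = classifier$classes)
  if (anyNA(y)) stop_wwpe("test labels contain classes unseen in training")
  pred <- factor(pred, levels = classifier$classes)
  confusion <- table(truth = y, predicted = pred)
  per_class <- diag(confusion) / rowSums(confusion)
  structure(
    list(confusion = confusion,
         per_class_accuracy = per_class,
         average_accuracy = sum(diag(confusion)) / sum(confusion),
         classifier_id = classifier$kind,
         n_test = length(y)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report [%s]: average accuracy %.3f on %d trials\n",
              x$classifier_id, x$average_accuracy, x$n_test))
  cat("per-class:", paste(sprintf("%s %.2f", names(x$per_class_accuracy),
                                  x$per_class_accuracy), collapse = ", "), "\n")
  invisible(x)
}

train_classifier <- function(kind, x, y, seed = 0L, params = list()) {
  switch(kind,
    svm = do.call(train_svm, c(list(x = x, y = y), params)),
    bpnn = do.call(train_bpnn, c(list(x = x, y = y, seed = seed), params)),
    stop_wwpe("unknown classifier \"%s\" (use \"svm\" or \"bpnn\")", kind)
  )
}

#' Compare feature sets across classifiers and split seeds
#'
#' Builds each feature matrix once, then for every (feature set, classifier,
#' seed) combination performs a stratified split, trains, and evaluates —
#' the grid used to compare the WWPE set against single sub-bands,
#' undecomposed entropies and the time-domain baseline.
#'
#' @param dataset An `emg_dataset` or list of trials.
#' @param specs List of [feature_spec()] objects.
#' @param classifiers Character vector among `"svm"`, `"bpnn"`.
#' @param seeds Integer vector of split (and network init) seeds.
#' @param train_fraction Passed to [stratified_split()].
#' @return A data.frame with one row per combination (`feature_set`,
#'   `classifier`, `seed`, `accuracy`); the full `evaluation_report` objects
#'   are attached as attribute `"reports"`.
#' @export
compare_feature_sets <- function(dataset, specs, classifiers = c("svm", "bpnn"),
                                 seeds = 0:4, train_fraction = 0.7) {
  if (length(specs) == 0L) stop_wwpe("need at least one feature_spec")
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  rows <- list()
  reports <- list()
  for (spec in specs) {
    fm <- build_feature_matrix(dataset, spec)
    for (seed in seeds) {
      sp <- stratified_split(fm$labels, train_fraction, seed)
      for (clf in classifiers) {
        fitted <- train_classifier(clf, fm$values[sp$train, , drop = FALSE],
                                   fm$labels[sp$train], seed = seed)
        rep <- evaluate(fitted, fm$values[sp$test, , drop = FALSE], fm$labels[sp$test])
        key <- sprintf("%s|%s|%d", fm$spec_id, clf, seed)
        reports[[key]] <- rep
        rows[[key]] <- data.frame(feature_set = fm$spec_id, classifier = clf,
                                  seed = seed, accuracy = rep$average_accuracy)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
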