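#' Configuration of a conventional-ML baseline
#'
#' @param method `"svm"`, `"rf"` or `"lda"`.
#' @param grid Named list of hyper-parameter candidate vectors searched on
#'   the validation subset. Defaults: svm `cost` 0.1/1/10 x `kernel`
#'   radial/linear; rf `ntree` 100/500 x `maxnodes` unlimited/32; lda
#'   `n_components` (PCA dimensions) `n_classes - 1`, 10 and 20.
#' @param n_selected_features Number of features kept by chi-square selection
#'   before SVM/RF (ignored for LDA, which uses PCA instead).
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(method = c("svm", "rf", "lda"), grid = NULL,
                            n_selected_features = 200L) {
  method <- match.arg(method)
  if (is.null(grid)) {
    grid <- switch(method,
      svm = list(cost = c(0.1, 1, 10), kernel = c("radial", "linear")),
      rf = list(ntree = c(100L, 500L), maxnodes = c(NA, 32L)),
      lda = list(n_components = NA))  # resolved per dataset
  }
  if (length(grid) == 0) stop("grid must be non-empty")
  if (n_selected_features < 1) stop("n_selected_features must be positive")
  structure(list(method = method, grid = grid,
                 n_selected_features = as.integer(n_selected_features)),
            class = "baseline_config")
}

#' Chi-square feature selection
#'
#' Scores every feature by the chi-square statistic of the
#' classes x (present, absent) contingency table built from min-max-scaled
#' intensities (the scaled intensity is treated as the "present" mass of a
#' sample, its complement as "absent"), and returns the indices of the `k`
#' highest-scoring features. Ties break towards the lower index; constant
#' features score zero.
#'
#' @param X Non-negative feature matrix (spectra in rows).
#' @param y Class labels (integer or factor).
#' @param k Number of features to keep (`<= ncol(X)`).
#' @return Integer vector of `k` feature indices, ordered by decreasing score.
#' @export
chi2_select <- function(X, y, k) {
  if (any(X < 0)) stop("chi-square selection requires non-negative features")
  if (k > ncol(X)) stop("k must not exceed the number of features")
  y <- as.integer(if (is.factor(y)) y else factor(y, levels = unique(y)))
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  S <- sweep(sweep(X, 2, lo, "-"), 2, rng, "/")
  classes <- sort(unique(y))
  O1 <- rowsum(S, y)                      # per-class "present" mass
  nc <- as.vector(table(factor(y, levels = classes)))
  O2 <- nc - O1                           # per-class "absent" mass
  T1 <- colSums(O1); n <- length(y)
  scores <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    t1 <- T1[j]
    if (t1 <= 0 || t1 >= n) next          # constant after scaling -> 0
    E1 <- nc * t1 / n
    E2 <- nc - E1
    scores[j] <- sum((O1[, j] - E1)^2 / E1 + (O2[, j] - E2)^2 / E2)
  }
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Fit and evaluate a conventional-ML baseline
#'
#' The comparison track: grid search scored on the validation subset, winner
#' refit on the training subset, metrics reported on the held-out test
#' subset. SVM and random forest are preceded by chi-square feature
#' selection (fitted on the training subset); LDA is preceded by PCA (also
#' fitted on train). Using the same [stratified_split()] object as the CNN
#' protocols makes the comparison paired: both tracks see byte-identical
#' index sets.
#'
#' @param ds A [spectra_dataset()] (scaled internally if not already), or the
#'   result of [preprocess_pipeline()] when `preprocessed = TRUE` inputs are
#'   prepared by the caller.
#' @param split A [stratified_split()].
#' @param method `"svm"`, `"rf"` or `"lda"`.
#' @param cfg A [baseline_config()] (defaults built for `method`).
#' @param preprocessed Run the five-step [preprocess_pipeline()] first and
#'   classify its peak-intensity features instead of the raw binned matrix.
#' @param preprocess_cfg A [preprocess_config()] used when
#'   `preprocessed = TRUE`.
#' @param seed Seed for the stochastic learners (random forest).
#' @return A [classification_metrics()] object with attributes
#'   `"best_params"` (winning grid point) and `"val_accuracy"`.
#' @export
fit_baseline <- function(ds, split, method = c("svm", "rf", "lda"),
                         cfg = NULL, preprocessed = FALSE,
                         preprocess_cfg = preprocess_config(), seed = 1L) {
  method <- match.arg(method)
  if (is.null(cfg)) cfg <- baseline_config(method)
  stopifnot(cfg$method == method)
  if (preprocessed) {
    X <- preprocess_pipeline(ds, preprocess_cfg)$features
  } else {
    if (!ds$scaled) ds <- scale_unit_interval(ds)
    X <- ds$matrix
  }
  y <- factor(ds$class_names[ds$labels], levels = ds$class_names)
  n_classes <- length(ds$class_names)
  if (length(unique(y[split$train])) < 2)
    stop("training subset must contain at least two classes")

  if (method %in% c("svm", "rf")) {
    keep <- chi2_select(X[split$train, , drop = FALSE], y[split$train],
                        k = min(cfg$n_selected_features, ncol(X)))
    X <- X[, keep, drop = FALSE]
  } else {
    grid <- cfg$grid
    if (length(grid$n_components) == 1 && is.na(grid$n_components))
      grid$n_components <- unique(pmin(c(n_classes - 1L, 10L, 20L),
                                       min(ncol(X), length(split$train)) - 1L))
    cfg$grid <- grid
    pca <- stats::prcomp(X[split$train, , drop = FALSE], center = TRUE,
                         scale. = FALSE)
    X <- scale(X, center = pca$center, scale = FALSE) %*% pca$rotation
  }

  fit_one <- function(params, rows) {
    set.seed(seed)
    if (method == "svm") {
      e1071::svm(x = X[rows, , drop = FALSE], y = y[rows],
                 cost = params$cost, kernel = as.character(params$kernel))
    } else if (method == "rf") {
      mn <- if (is.na(params$maxnodes)) NULL else params$maxnodes
      randomForest::randomForest(x = X[rows, , drop = FALSE], y = y[rows],
                                 ntree = params$ntree, maxnodes = mn)
    } else {
      nc <- params$n_components
      MASS::lda(X[rows, seq_len(nc), drop = FALSE], grouping = y[rows])
    }
  }
  predict_one <- function(fit, params, rows) {
    if (method == "lda") {
      as.character(stats::predict(
        fit, X[rows, seq_len(params$n_components), drop = FALSE])$class)
    } else {
      as.character(stats::predict(fit, X[rows, , drop = FALSE]))
    }
  }

  combos <- expand.grid(cfg$grid, stringsAsFactors = FALSE)
  best <- NULL
  for (ci in seq_len(nrow(combos))) {
    params <- combos[ci, , drop = FALSE]
    fit <- fit_one(params, split$train)
    vacc <- mean(predict_one(fit, params, split$validation) ==
                 as.character(y[split$validation]))
    if (is.null(best) || vacc > best$vacc)
      best <- list(params = params, vacc = vacc)
  }
  fit <- fit_one(best$params, split$train)
  pred <- predict_one(fit, best$params, split$test)
  metrics <- classification_metrics(
    as.integer(y[split$test]),
    as.integer(factor(pred, levels = ds$class_names)),
    n_classes = n_classes, class_names = ds$class_names)
  attr(metrics, "best_params") <- best$params
  attr(metrics, "val_accuracy") <- best$vacc
  metrics
}
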