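#' Decoding study configuration
#'
#' Settings of the classification study: the classifier set, stratified
#' cross-validation folds, train/test fraction, PCA dimensionality, the SVM
#' hyperparameter grid and the number of channels picked by sequential
#' forward selection.
#'
#' @param classifiers Subset of `"KNN"`, `"SVM"`, `"NB"`, `"LDA"`, `"QLDA"`.
#' @param k_folds Stratified cross-validation folds.
#' @param test_fraction Held-out test fraction of the stratified split.
#' @param pca_components Number of principal components kept.
#' @param svm_grid Data.frame `kernel`, `cost`, `gamma` (`NA` gamma = the
#'   scale heuristic `1 / (p * var(X))`).
#' @param n_select Channels picked by sequential forward selection.
#' @param knn_k Neighbours for KNN.
#' @param sfs_classifier Classifier scoring the selection steps.
#' @param seed Integer seed for splits, folds and tie-breaks.
#' @return An object of class `decode_config`.
#' @export
decode_config <- function(classifiers = c("KNN", "SVM", "NB", "LDA", "QLDA"),
                          k_folds = 10, test_fraction = 0.2,
                          pca_components = 2,
                          svm_grid = default_svm_grid(),
                          n_select = 5, knn_k = 5,
                          sfs_classifier = "KNN", seed = 1L) {
  stopifnot(k_folds >= 2, test_fraction > 0, test_fraction < 1,
            all(classifiers %in% c("KNN", "SVM", "NB", "LDA", "QLDA")))
  cfg <- list(classifiers = classifiers, k_folds = k_folds,
              test_fraction = test_fraction, pca_components = pca_components,
              svm_grid = svm_grid, n_select = n_select, knn_k = knn_k,
              sfs_classifier = sfs_classifier, seed = as.integer(seed))
  class(cfg) <- "decode_config"
  cfg
}

#' @rdname decode_config
#' @export
default_svm_grid <- function() {
  rbind(
    expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100), gamma = NA,
                stringsAsFactors = FALSE),
    expand.grid(kernel = "radial", cost = c(0.1, 1, 10, 100),
                gamma = c(NA, 0.01, 0.1, 1), stringsAsFactors = FALSE)
  )
}

#' Balanced accuracy
#'
#' The mean over classes of the per-class recall (proportion correct within
#' each true class); equal to plain accuracy on exactly balanced data, with
#' chance level `1 / n_classes`.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Declared class set; every class must occur in `y_true`.
#' @return A fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred, classes = sort(unique(y_true))) {
  if (length(y_true) == 0) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  recalls <- vapply(classes, function(cl) {
    sel <- y_true == cl
    if (!any(sel)) stop("class ", cl, " absent from y_true")
    mean(y_pred[sel] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Confusion matrix over a fixed class order
#'
#' @param y_true,y_pred Label vectors.
#' @param class_order Row/column order; rows = true class, columns =
#'   predicted.
#' @return Integer matrix of counts.
#' @export
confusion_matrix <- function(y_true, y_pred,
                             class_order = condition_names()) {
  unknown <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  m <- table(factor(y_true, class_order), factor(y_pred, class_order))
  matrix(as.integer(m), length(class_order), length(class_order),
         dimnames = list(true = class_order, predicted = class_order))
}

#' Stratified train/test split
#'
#' Splits indices so per-class proportions are preserved to within one
#' trial; the shuffle is seeded.
#'
#' @param labels Per-trial labels.
#' @param test_fraction Fraction held out.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  test <- integer(0)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_test <- round(length(idx) * test_fraction)
      if (n_test < 1)
        stop("class ", cl, " too small for test fraction ", test_fraction)
      test <- c(test, sample(idx, n_test))
    }
  })
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# stratified fold assignment: per class, shuffled then dealt round-robin
stratified_folds <- function(labels, k, seed = NULL) {
  assign_folds <- function() {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

#' PCA projection fitted on training rows only
#'
#' Mean-centres with the training means and projects on the leading
#' eigenvectors of the training covariance. Fitting never sees `apply_x`,
#' which keeps the train/test separation leak-free.
#'
#' @param train_x Training feature matrix.
#' @param apply_x Optional matrix projected with the fitted transform.
#' @param n_components Components kept.
#' @return List with `train_scores`, `apply_scores` (or `NULL`), `rotation`,
#'   `center`, `sdev`.
#' @export
pca_project <- function(train_x, apply_x = NULL, n_components = 2) {
  stopifnot(n_components <= min(dim(train_x)))
  if (all(apply(train_x, 2, stats::var) < 1e-24))
    stop("degenerate features: training columns are constant, PCA undefined")
  pc <- stats::prcomp(train_x, center = TRUE, scale. = FALSE)
  list(train_scores = pc$x[, seq_len(n_components), drop = FALSE],
       apply_scores = if (!is.null(apply_x))
         stats::predict(pc, apply_x)[, seq_len(n_components), drop = FALSE],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       center = pc$center, sdev = pc$sdev)
}

# Gaussian discriminant classifier (pooled covariance = linear, per-class =
# quadratic). Falls back to a ridge on the covariance when it is singular or
# ill-conditioned (e.g. more channels than trials), with a warning.
gaussian_discriminant <- function(x_train, y_train, x_test, pooled = TRUE) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  classes <- sort(unique(y_train))
  p <- ncol(x_train)
  means <- lapply(classes, function(cl) colMeans(x_train[y_train == cl, , drop = FALSE]))
  covs <- lapply(classes, function(cl) {
    xc <- x_train[y_train == cl, , drop = FALSE]
    stats::cov(xc)
  })
  if (pooled) {
    ns <- vapply(classes, function(cl) sum(y_train == cl), numeric(1))
    pool <- Reduce(`+`, Map(function(s, n) s * (n - 1), covs, ns)) /
      (nrow(x_train) - length(classes))
    covs <- rep(list(pool), length(classes))
  }
  singular <- FALSE
  covs <- lapply(covs, function(s) {
    ok <- tryCatch(rcond(s) > 1e-10, error = function(e) FALSE)
    if (!ok) {
      singular <<- TRUE
      s + diag(mean(diag(s)) * 1e-3 + 1e-12, nrow(s))
    } else s
  })
  if (singular)
    warning("singular covariance; applying ridge regularisation",
            call. = FALSE)
  priors <- vapply(classes, function(cl) mean(y_train == cl), numeric(1))
  scores <- vapply(seq_along(classes), function(j) {
    ch <- chol(covs[[j]])
    d <- forwardsolve(t(ch), t(x_test) - means[[j]])
    -sum(log(diag(ch))) - 0.5 * colSums(d^2) + log(priors[j])
  }, numeric(nrow(x_test)))
  scores <- matrix(scores, nrow = nrow(x_test))
  classes[max.col(scores, ties.method = "first")]
}

#' Fit a classifier and predict test labels
#'
#' One entry point for the five classifier families of the study: KNN
#' (majority vote over `k` Euclidean neighbours), SVM (maximum-margin,
#' one-vs-one for 3 classes), Gaussian Naive Bayes, and linear/quadratic
#' Gaussian discriminants (pooled / per-class covariance, with a documented
#' ridge fallback for singular covariances).
#'
#' @param classifier One of `"KNN"`, `"SVM"`, `"NB"`, `"LDA"`, `"QLDA"`.
#' @param x_train,y_train Training features and labels.
#' @param x_test Test features.
#' @param hyper Named list of hyperparameters (`k` for KNN; `kernel`,
#'   `cost`, `gamma` for SVM).
#' @return Character vector of predicted labels.
#' @export
fit_predict <- function(classifier, x_train, y_train, x_test, hyper = list()) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- as.character(y_train)
  switch(classifier,
    KNN = as.character(class::knn(x_train, x_test, factor(y_train),
                                  k = hyper$k %||% 5)),
    SVM = {
      gamma <- hyper$gamma
      if (is.null(gamma) || is.na(gamma))
        gamma <- 1 / (ncol(x_train) * max(stats::var(as.vector(x_train)), 1e-12))
      fit <- e1071::svm(x_train, factor(y_train),
                        kernel = hyper$kernel %||% "radial",
                        cost = hyper$cost %||% 1, gamma = gamma,
                        scale = FALSE)
      as.character(stats::predict(fit, x_test))
    },
    NB = {
      fit <- e1071::naiveBayes(x_train, factor(y_train))
      as.character(stats::predict(fit, x_test))
    },
    LDA = gaussian_discriminant(x_train, y_train, x_test, pooled = TRUE),
    QLDA = gaussian_discriminant(x_train, y_train, x_test, pooled = FALSE),
    stop("unknown classifier: ", classifier)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold cross-validated balanced accuracy
#'
#' @param classifier Classifier name (see [fit_predict()]).
#' @param x,y Features and labels.
#' @param k Folds; every class must have at least `k` members.
#' @param seed Integer seed for the fold assignment.
#' @param hyper Hyperparameters passed to [fit_predict()].
#' @param folds Optional precomputed fold assignment (overrides `seed`).
#' @return Numeric vector of `k` per-fold balanced accuracies.
#' @export
cross_validate <- function(classifier, x, y, k = 10, seed = 1L,
                           hyper = list(), folds = NULL) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < k))
    stop("every class needs >= k trials for ", k, "-fold stratified CV")
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  vapply(seq_len(k), function(f) {
    tr <- folds != f
    pred <- withr::with_seed(seed + f, suppressWarnings(
      fit_predict(classifier, x[tr, , drop = FALSE], y[tr],
                  x[!tr, , drop = FALSE], hyper)))
    balanced_accuracy(y[!tr], pred, classes = sort(unique(y)))
  }, numeric(1))
}

#' Grid search for SVM hyperparameters
#'
#' Evaluates every grid point by stratified k-fold cross-validated balanced
#' accuracy and returns the best; ties are broken by grid order (first
#' wins).
#'
#' @param x,y Features and labels.
#' @param grid Data.frame `kernel`, `cost`, `gamma`.
#' @param k Folds.
#' @param seed Integer seed (same folds for every grid point).
#' @return List with `kernel`, `cost`, `gamma`, `mean_bacc`, `fold_bacc`
#'   and the full `table` of per-point mean accuracies.
#' @export
grid_search_svm <- function(x, y, grid = default_svm_grid(), k = 10, seed = 1L) {
  if (nrow(grid) == 0) stop("empty grid")
  folds <- stratified_folds(as.character(y), k, seed)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    hyper <- list(kernel = grid$kernel[i], cost = grid$cost[i],
                  gamma = grid$gamma[i])
    cross_validate("SVM", x, y, k, seed, hyper, folds = folds)
  })
  means <- vapply(res, mean, numeric(1))
  best <- which.max(means)   # first maximum wins
  list(kernel = grid$kernel[best], cost = grid$cost[best],
       gamma = grid$gamma[best], mean_bacc = means[best],
       fold_bacc = res[[best]],
       table = cbind(grid, mean_bacc = means))
}

#' Sequential forward channel selection
#'
#' Greedy selection: starting from the empty set, each step adds the channel
#' that maximises the cross-validated balanced accuracy of the augmented
#' set; ties are broken by lower channel index. Candidate sets are scored by
#' leave-one-out cross-validation with predictions pooled into a single
#' balanced accuracy: with only 60 trials, the marginal gain of one channel
#' is on the order of one or two correctly recovered trials, which
#' fold-assignment noise in a coarse k-fold score would swamp; the
#' leave-one-out score has no fold randomness at all. The default KNN
#' scorer penalises irrelevant channels naturally, since they dilute the
#' neighbour distances.
#'
#' @param x Trials x channels feature matrix with channel `colnames`.
#' @param y Labels.
#' @param n_select Channels to select.
#' @param classifier Scoring classifier (see [fit_predict()]).
#' @param seed Integer seed (classifier tie-breaks only).
#' @param hyper Hyperparameters for the scoring classifier.
#' @return Character vector of selected channel names, in selection order,
#'   with attribute `scores` (leave-one-out score after each addition).
#' @export
sequential_forward_selection <- function(x, y, n_select = 5,
                                         classifier = "KNN",
                                         seed = 1L, hyper = list()) {
  stopifnot(n_select <= ncol(x))
  y <- as.character(y)
  n <- nrow(x)
  classes <- sort(unique(y))
  loo_score <- function(cols) {
    xs <- x[, cols, drop = FALSE]
    pred <- withr::with_seed(seed, vapply(seq_len(n), function(i)
      suppressWarnings(fit_predict(classifier, xs[-i, , drop = FALSE],
                                   y[-i], xs[i, , drop = FALSE], hyper)),
      character(1)))
    balanced_accuracy(y, pred, classes = classes)
  }
  selected <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(n_select)) {
    cand <- setdiff(seq_len(ncol(x)), selected)
    cand_scores <- vapply(cand, function(j) loo_score(c(selected, j)),
                          numeric(1))
    best <- cand[which.max(cand_scores)]  # first maximum = lowest index
    selected <- c(selected, best)
    scores <- c(scores, max(cand_scores))
  }
  structure(colnames(x)[selected], scores = scores)
}

#' Window-sweep classification study
#'
#' For every 100 ms window of the grid and every configured classifier,
#' extracts max-amplitude features and records the stratified k-fold
#' cross-validated balanced accuracy. The best window is the one with the
#' highest mean accuracy across classifiers (ties go to the earlier
#' window). The sweep scores each classifier on all 64 channels without
#' PCA.
#'
#' @param epochs Baseline-corrected 1 s `epochs` (`t_start = 0`).
#' @param config A [decode_config()].
#' @param windows A [window_grid()] data.frame.
#' @return An object of class `decode_sweep`: list with `table` (window x
#'   classifier rows: `start`, `end`, `classifier`, `mean_bacc`, `sd_bacc`),
#'   `folds` (named list of per-fold accuracy vectors), `best_window`
#'   (`c(start, end)`), `window_means`.
#' @export
sweep_windows <- function(epochs, config = decode_config(),
                          windows = window_grid()) {
  rows <- list(); folds <- list()
  for (w in seq_len(nrow(windows))) {
    X <- max_amplitude_features(epochs, c(windows$start[w], windows$end[w]))
    y <- attr(X, "labels")
    for (cl in config$classifiers) {
      hyper <- if (cl == "KNN") list(k = config$knn_k) else list()
      b <- cross_validate(cl, X, y, config$k_folds,
                          stage_seed(config$seed, 3), hyper)
      key <- paste0(windows$start[w], "-", windows$end[w], ":", cl)
      folds[[key]] <- b
      rows[[key]] <- data.frame(start = windows$start[w], end = windows$end[w],
                                classifier = cl, mean_bacc = mean(b),
                                sd_bacc = stats::sd(b))
    }
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  wm <- vapply(seq_len(nrow(windows)), function(w) {
    mean(tab$mean_bacc[tab$start == windows$start[w]])
  }, numeric(1))
  best <- which.max(wm)      # first maximum = earlier window
  out <- list(table = tab, folds = folds,
              best_window = c(windows$start[best], windows$end[best]),
              window_means = data.frame(start = windows$start,
                                        end = windows$end, mean_bacc = wm))
  class(out) <- "decode_sweep"
  out
}

#' Final held-out test of the decoding pipeline
#'
#' The end-to-end classification protocol: max-amplitude features in the
#' chosen window, a stratified 80/20 split, PCA (2 components) fitted on the
#' training rows only, SVM hyperparameters grid-searched by stratified
#' k-fold cross-validation on the training scores, and balanced accuracy
#' plus the confusion matrix on the untouched test rows. All fitting uses
#' training rows only.
#'
#' @param epochs_augmented Augmented 1 s `epochs` (the 120-trial set).
#' @param best_window `c(start, end)` ms, normally from [sweep_windows()].
#' @param config A [decode_config()].
#' @return List with `test_bacc`, `confusion`, `validation_bacc`
#'   (mean cross-validated accuracy of the winning hyperparameters),
#'   `validation_sd`, `hyper`, `split`, `pca`.
#' @export
final_test <- function(epochs_augmented, best_window, config = decode_config()) {
  X <- max_amplitude_features(epochs_augmented, best_window)
  y <- attr(X, "labels")
  split <- stratified_split(y, config$test_fraction,
                            stage_seed(config$seed, 4))
  pca <- pca_project(X[split$train, , drop = FALSE],
                     X[split$test, , drop = FALSE],
                     config$pca_components)
  gs <- grid_search_svm(pca$train_scores, y[split$train], config$svm_grid,
                        config$k_folds, stage_seed(config$seed, 5))
  hyper <- gs[c("kernel", "cost", "gamma")]
  pred <- fit_predict("SVM", pca$train_scores, y[split$train],
                      pca$apply_scores, hyper)
  list(test_bacc = balanced_accuracy(y[split$test], pred),
       confusion = confusion_matrix(y[split$test], pred),
       validation_bacc = gs$mean_bacc,
       validation_sd = stats::sd(gs$fold_bacc),
       hyper = hyper, split = split, pca = pca)
}
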