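three <- c("INNO", "MOD", "NOX")

test_that("balanced accuracy is the mean of per-class recalls", {
  y <- rep(three, each = 4)
  expect_equal(balanced_accuracy(y, y), 1)
  expect_equal(balanced_accuracy(y, rep("MOD", 12)), 1 / 3)
  # equals plain accuracy on balanced labels
  withr::with_seed(1, pred <- sample(three, 12, replace = TRUE))
  expect_equal(balanced_accuracy(y, pred), mean(y == pred))
  # and differs from it on unbalanced ones in the expected direction
  yu <- c(rep("INNO", 8), rep("MOD", 2), rep("NOX", 2))
  pu <- rep("INNO", 12)
  expect_equal(balanced_accuracy(yu, pu), 1 / 3)
  expect_error(balanced_accuracy(character(0), character(0)), "empty")
})

test_that("confusion matrix counts every (true, predicted) pair", {
  withr::with_seed(2, {
    y <- sample(rep(three, each = 10))
    p <- sample(three, 30, replace = TRUE)
  })
  cm <- confusion_matrix(y, p)
  for (i in three) for (j in three)
    expect_equal(cm[i, j], sum(y == i & p == j))
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(factor(y, three)))))
  perfect <- confusion_matrix(y, y)
  expect_equal(unname(perfect), diag(as.vector(table(factor(y, three)))))
  expect_error(confusion_matrix(c(y, "SHAM"), c(p, "MOD")), "unknown label")
})

test_that("stratified splitting preserves class balance and is seeded", {
  y <- rep(three, each = 40)
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_length(sp$test, 24)
  expect_equal(as.vector(table(y[sp$test])), rep(8L, 3))
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(y, 0.2, seed = 3))
  expect_false(identical(sp$test, stratified_split(y, 0.2, seed = 4)$test))
  expect_error(stratified_split(c("A", "A", "B"), 0.2), "too small")
})

test_that("stratified folds partition every class across folds", {
  y <- rep(three, each = 20)
  f <- painmark:::stratified_folds(y, 10, seed = 1)
  expect_setequal(unique(f), 1:10)
  for (k in 1:10) expect_equal(as.vector(table(y[f == k])), rep(2L, 3))
})

test_that("PCA is fitted on training rows only and matches eigen analysis", {
  withr::with_seed(4, X <- matrix(stats::rnorm(40 * 6), 40))
  pc <- pca_project(X[1:30, ], X[31:40, ], 2)
  expect_lt(max(abs(colMeans(pc$train_scores))), 1e-9)
  ev <- eigen(stats::cov(X[1:30, ]))$values[1:2]
  expect_equal(unname(apply(pc$train_scores, 2, stats::var)), ev,
               tolerance = 1e-10)
  # intrinsic rank 2 reconstructs exactly from 2 scores
  B <- matrix(stats::rnorm(12), 6, 2)
  Z <- matrix(stats::rnorm(60), 30, 2)
  low <- Z %*% t(B)
  pc2 <- pca_project(low, n_components = 2)
  rec <- pc2$train_scores %*% t(pc2$rotation) +
    matrix(pc2$center, 30, 6, byrow = TRUE)
  expect_equal(rec, low, tolerance = 1e-8)
  expect_error(pca_project(matrix(1, 10, 3)), "degenerate")
})

test_that("classifier families behave as specified on constructed data", {
  withr::with_seed(5, {
    Xtr <- rbind(matrix(stats::rnorm(60, 0), 30), matrix(stats::rnorm(60, 10), 30))
    ytr <- rep(c("A", "B"), each = 30)
  })
  # a point's nearest neighbour is itself
  expect_equal(balanced_accuracy(ytr, fit_predict("KNN", Xtr, ytr, Xtr,
                                                  list(k = 1))), 1)
  # far-separated Gaussians are almost perfectly linearly separable
  withr::with_seed(6, {
    mk <- function(mu, n) cbind(stats::rnorm(n, mu), stats::rnorm(n, 0))
    Xb <- rbind(mk(0, 200), mk(10, 200))
    yb <- rep(c("A", "B"), each = 200)
    Xt <- rbind(mk(0, 200), mk(10, 200))
    yt <- rep(c("A", "B"), each = 200)
  })
  expect_gt(balanced_accuracy(yt, fit_predict("LDA", Xb, yb, Xt)), 0.99)
  expect_error(fit_predict("tree", Xtr, ytr, Xtr), "unknown classifier")
})

test_that("in-package discriminants agree with the reference implementations", {
  skip_if_not_installed("MASS")
  withr::with_seed(7, {
    X <- rbind(matrix(stats::rnorm(100, 0), 50),
               matrix(stats::rnorm(100, 2), 50),
               matrix(stats::rnorm(100, 4), 50))
    y <- rep(three, each = 50)
    Xt <- X + stats::rnorm(300, sd = 0.3)
  })
  mine_l <- fit_predict("LDA", X, y, Xt)
  ref_l <- as.character(stats::predict(MASS::lda(X, y), Xt)$class)
  expect_gt(mean(mine_l == ref_l), 0.99)
  mine_q <- fit_predict("QLDA", X, y, Xt)
  ref_q <- as.character(stats::predict(MASS::qda(X, y), Xt)$class)
  expect_gt(mean(mine_q == ref_q), 0.99)
})

test_that("singular covariances trigger the ridge fallback with a warning", {
  withr::with_seed(8, X <- matrix(stats::rnorm(12 * 20), 12))  # p > n per class
  y <- rep(c("A", "B"), each = 6)
  expect_warning(pred <- fit_predict("QLDA", X, y, X), "ridge")
  expect_length(pred, 12)
})

test_that("cross-validation scores stay near chance on noise, high on signal", {
  y <- rep(three, each = 10)
  nulls <- vapply(1:30, function(s) {
    X <- withr::with_seed(100 + s, matrix(stats::rnorm(30 * 4), 30))
    mean(cross_validate("LDA", X, y, k = 5, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 1 / 3), 3 * stats::sd(nulls) / sqrt(30))

  Xsig <- withr::with_seed(9, matrix(stats::rnorm(30 * 4), 30) +
                             outer(as.numeric(factor(y)) * 5, rep(1, 4)))
  b <- cross_validate("LDA", Xsig, y, k = 5, seed = 1)
  expect_length(b, 5)
  expect_true(all(b >= 0 & b <= 1))
  expect_gt(mean(b), 0.95)
  expect_error(cross_validate("LDA", Xsig, y, k = 12, seed = 1), "stratified CV")
})

test_that("SVM grid search returns the exhaustive-evaluation maximum", {
  withr::with_seed(10, {
    X <- matrix(stats::rnorm(60 * 2), 60) +
      outer(as.numeric(factor(rep(three, each = 20))) * 2, c(1, 0))
  })
  y <- rep(three, each = 20)
  grid <- expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 10),
                      gamma = 0.5, stringsAsFactors = FALSE)
  gs <- grid_search_svm(X, y, grid, k = 5, seed = 2)
  folds <- painmark:::stratified_folds(y, 5, 2)
  oracle <- vapply(seq_len(nrow(grid)), function(i)
    mean(cross_validate("SVM", X, y, 5, 2,
                        list(kernel = grid$kernel[i], cost = grid$cost[i],
                             gamma = grid$gamma[i]), folds = folds)),
    numeric(1))
  expect_equal(gs$mean_bacc, max(oracle))
  expect_equal(which(oracle == max(oracle))[1],
               which(gs$table$mean_bacc == gs$mean_bacc)[1])

  single <- grid[2, ]
  g1 <- grid_search_svm(X, y, single, k = 5, seed = 2)
  expect_equal(g1$kernel, single$kernel)
  expect_equal(g1$cost, single$cost)
  dup <- rbind(grid[1, ], grid[1, ])
  gd <- grid_search_svm(X, y, dup, k = 5, seed = 2)
  expect_equal(unlist(gd[c("kernel", "cost")]),
               unlist(grid[1, c("kernel", "cost")]))
  expect_error(grid_search_svm(X, y, grid[0, ], k = 5), "empty grid")
})

test_that("sequential forward selection is greedy with an exhaustive first step", {
  withr::with_seed(11, {
    X <- matrix(stats::rnorm(60 * 8), 60)
    colnames(X) <- paste0("ch", 1:8)
    y <- rep(three, each = 20)
    X[, 3] <- X[, 3] + as.numeric(factor(y)) * 3   # ch3 is the signal
  })
  sel <- sequential_forward_selection(X, y, 3, seed = 1)
  expect_equal(sel[1], "ch3")
  # brute-force first-step oracle: leave-one-out KNN score per single channel
  loo1 <- vapply(seq_len(ncol(X)), function(j) {
    pred <- vapply(seq_len(60), function(i)
      as.character(class::knn(X[-i, j, drop = FALSE], X[i, j, drop = FALSE],
                              factor(y[-i]), k = 5)), character(1))
    balanced_accuracy(y, pred)
  }, numeric(1))
  expect_equal(sel[1], colnames(X)[which.max(loo1)])

  all_sel <- sequential_forward_selection(X, y, ncol(X), seed = 1)
  expect_setequal(all_sel, colnames(X))
})

test_that("selection recovers central channels when the signal lives there", {
  # the three central channels share a graded class contrast over a noisy
  # background; everything else is pure noise
  withr::with_seed(12, {
    n <- 120
    X <- matrix(stats::rnorm(n * 16, sd = 1.5), n)
    colnames(X) <- c("Cz", "C4", "C6", paste0("noise", 1:13))
    y <- rep(three, each = n / 3)
    lev <- c(INNO = 0, MOD = 3, NOX = 6)
    for (ch in c("Cz", "C4", "C6")) X[, ch] <- X[, ch] + lev[y]
  })
  sel <- sequential_forward_selection(X, y, 5, seed = 1)
  expect_true(all(c("Cz", "C4", "C6") %in% sel))
})

test_that("the window sweep localises a planted discriminative window", {
  n_tr <- 60
  withr::with_seed(13, {
    data <- array(stats::rnorm(n_tr * 4 * 500), c(n_tr, 4, 500))
    y <- rep(three, n_tr / 3)
    t_ms <- (0:499) * 2
    bump <- 4 * exp(-(t_ms - 700)^2 / (2 * 20^2))
    for (i in which(y == "NOX")) data[i, 1, ] <- data[i, 1, ] + bump
  })
  ep <- new_epochs(data, t_start = 0, labels = y)
  cfg <- decode_config(classifiers = c("KNN", "LDA", "NB"), seed = 2)
  sw <- sweep_windows(ep, cfg)
  expect_equal(sw$best_window, c(650, 750))
  expect_equal(nrow(sw$table), 9 * 3)
  expect_equal(length(sw$folds), 27)

  # pure-noise epochs hover at the 3-class chance level in every cell
  ep0 <- rand_epochs(60, 4, 500, t_start = 0,
                     labels = rep(three, 20), seed = 14)
  sw0 <- sweep_windows(ep0, cfg)
  expect_lt(abs(mean(sw0$table$mean_bacc) - 1 / 3), 0.06)
  expect_true(all(abs(sw0$table$mean_bacc - 1 / 3) < 0.25))
})

test_that("the final test is leak-free and near chance under label shuffling", {
  n <- 120
  withr::with_seed(15, {
    y <- rep(three, each = 40)
    data <- array(stats::rnorm(n * 6 * 500), c(n, 6, 500))
    # separable class structure in the [650, 750) window on channels 1-2
    t_ms <- (0:499) * 2
    bump <- exp(-(t_ms - 700)^2 / (2 * 30^2))
    for (i in seq_len(n)) {
      amp <- c(INNO = 0, MOD = 4, NOX = 8)[y[i]]
      data[i, 1, ] <- data[i, 1, ] + amp * bump
      data[i, 2, ] <- data[i, 2, ] + amp * bump
    }
  })
  ep <- new_epochs(data, t_start = 0, labels = y)
  cfg <- decode_config(seed = 3)
  ft <- final_test(ep, c(650, 750), cfg)
  expect_gt(ft$test_bacc, 0.9)
  expect_equal(unname(rowSums(ft$confusion)), rep(8L, 3))
  expect_equal(sum(ft$confusion), 24)

  # corrupting test rows must not change anything fitted on training rows
  ep2 <- ep
  ep2$data[ft$split$test, , ] <- ep2$data[ft$split$test, , ] * 10 + 3
  ft2 <- final_test(ep2, c(650, 750), cfg)
  expect_identical(ft$split, ft2$split)
  expect_equal(ft$pca$rotation, ft2$pca$rotation)
  expect_equal(ft$pca$center, ft2$pca$center)
  expect_identical(ft$hyper, ft2$hyper)
  expect_equal(ft$validation_bacc, ft2$validation_bacc)

  shuffled <- ep
  shuffled$labels <- withr::with_seed(16, sample(ep$labels))
  fts <- final_test(shuffled, c(650, 750), cfg)
  expect_lt(fts$test_bacc, 0.65)
})
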