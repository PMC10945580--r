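# Classifier families behind the two-layer model. Random forest (ranger)
# is the default; SVM (e1071) and single-hidden-layer MLP (nnet) are
# optional. All fits are deterministic under a fixed seed.

default_grid <- function(family) {
  switch(family,
    random_forest = expand.grid(num.trees = c(100L, 300L),
                                max.depth = c(0L, 16L)),
    svm = expand.grid(cost = c(1, 10)),
    mlp = expand.grid(size = c(4L, 8L)))
}

default_params <- function(family) {
  switch(family,
    random_forest = list(num.trees = 300L, max.depth = 0L),
    svm = list(cost = 1),
    mlp = list(size = 8L))
}

fit_pixel_classifier <- function(X, y, family, params, seed) {
  y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; cannot fit a classifier")
  if (family == "random_forest") {
    fit <- ranger::ranger(x = as.data.frame(X), y = factor(y, c(FALSE, TRUE)),
                          probability = TRUE, num.trees = params$num.trees,
                          max.depth = params$max.depth, seed = seed,
                          num.threads = 1L, verbose = FALSE)
  } else if (family == "svm") {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("family 'svm' requires the e1071 package")
    set.seed(seed)
    fit <- e1071::svm(x = X, y = factor(y, c(FALSE, TRUE)), cost = params$cost,
                      probability = TRUE, scale = FALSE)
  } else if (family == "mlp") {
    if (!requireNamespace("nnet", quietly = TRUE))
      stop("family 'mlp' requires the nnet package")
    set.seed(seed)
    fit <- nnet::nnet(x = X, y = as.numeric(y), size = params$size,
                      decay = 1e-4, maxit = 200, trace = FALSE,
                      MaxNWts = 1e5)
  } else stop("unknown classifier family: ", family)
  structure(list(fit = fit, family = family, params = params,
                 n_features = ncol(X)), class = "pixel_classifier")
}

predict_pixel_prob <- function(clf, X) {
  stopifnot(inherits(clf, "pixel_classifier"))
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != clf$n_features)
    stop("feature dimension mismatch: model expects ", clf$n_features,
         ", got ", ncol(X))
  if (clf$family == "random_forest") {
    pr <- predict(clf$fit, data = as.data.frame(X), num.threads = 1L,
                  verbose = FALSE)$predictions
    unname(pr[, "TRUE"])
  } else if (clf$family == "svm") {
    requireNamespace("e1071", quietly = TRUE)  # registers predict.svm
    pr <- attr(predict(clf$fit, X, probability = TRUE), "probabilities")
    unname(pr[, "TRUE"])
  } else {
    requireNamespace("nnet", quietly = TRUE)
    as.numeric(predict(clf$fit, X))
  }
}

f1_score <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# Grid-search hyperparameter optimization with stratified k-fold CV,
# selecting on F1 of the positive class.
tune_pixel_classifier <- function(X, y, family, grid = NULL, folds = 5L,
                                  seed = 0L) {
  grid <- grid %||% default_grid(family)
  y <- as.logical(y)
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    i <- which(y == cls)
    fold_of[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    fs <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold_of != k
      if (length(unique(y[tr])) < 2L || !any(!tr)) { fs[k] <- NA; next }
      clf <- fit_pixel_classifier(X[tr, , drop = FALSE], y[tr], family,
                                  params, seed = seed + k)
      pr <- predict_pixel_prob(clf, X[!tr, , drop = FALSE])
      fs[k] <- f1_score(pr >= 0.5, y[!tr])
    }
    scores[g] <- mean(fs, na.rm = TRUE)
  }
  best <- which.max(scores)
  list(params = as.list(grid[best, , drop = FALSE]),
       cv = cbind(grid, f1 = scores))
}
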