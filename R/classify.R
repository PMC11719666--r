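#' Stratified train/test split
#'
#' Deterministic 70/30 (by default) split, stratified by label: each
#' class contributes `round(train_fraction * n_class)` training samples.
#'
#' @param data tibble with a label column.
#' @param train_fraction fraction per class in the training set.
#' @param seed RNG seed.
#' @param label_col name of the label column.
#' @return A list of class `split_spec`: `train`, `test` (tibbles),
#'   `seed`, `train_fraction`.
#' @export
stratified_split <- function(data, train_fraction = 0.7, seed = 42,
                             label_col = "label") {
  labels <- as.factor(data[[label_col]])
  if (any(table(labels) < 2)) {
    rlang::abort("Every class needs at least 2 members to be split.")
  }
  train_idx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- max(1L, min(n_tr, length(idx) - 1L))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  structure(
    list(
      train = data[train_idx, , drop = FALSE],
      test = data[-train_idx, , drop = FALSE],
      seed = as.integer(seed), train_fraction = train_fraction
    ),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf(
    "<split_spec> %d train / %d test (fraction %.2f, seed %d)\n",
    nrow(x$train), nrow(x$test), x$train_fraction, x$seed
  ))
  invisible(x)
}

#' Train and evaluate one classifier
#'
#' Fits one of the four reverse-validation model families on the
#' training table and reports train/test accuracy and the test confusion
#' matrix. Features are autoscaled with training-set statistics only.
#' Pinned defaults: `BP` is a single-hidden-layer (16 unit) neural
#' network trained by backpropagation (`nnet`); `SVM` is an RBF-kernel
#' C-classifier (`e1071`); `RF` is a 500-tree random forest
#' (`randomForest`); `DBN` is two stacked binary RBMs (64 and 32 hidden
#' units, contrastive-divergence-1 pretraining on min--max scaled
#' features) with a softmax output layer and full backpropagation
#' fine-tuning, implemented in the package.
#'
#' @param model_kind one of `"BP"`, `"SVM"`, `"DBN"`, `"RF"`.
#' @param train,test tibbles (e.g. from [stratified_split()]).
#' @param seed RNG seed for the stochastic learners.
#' @param label_col name of the label column.
#' @param columns optional explicit feature columns.
#' @return An object of class `eval_report`: `model_kind`, `seed`,
#'   `train_accuracy`, `test_accuracy` (percent), `confusion`
#'   (rows = true classes), `n_train`, `n_test`.
#' @export
train_eval <- function(model_kind, train, test, seed = 42,
                       label_col = "label", columns = NULL) {
  kinds <- c("BP", "SVM", "DBN", "RF")
  if (!is.character(model_kind) || length(model_kind) != 1 || !model_kind %in% kinds) {
    rlang::abort(sprintf(
      "Unknown model_kind '%s'; valid kinds: %s",
      paste(model_kind, collapse = ","), paste(kinds, collapse = ", ")
    ))
  }
  if (is.null(columns)) columns <- feature_columns(train)
  ytr <- as.factor(train[[label_col]])
  yte <- factor(test[[label_col]], levels = levels(ytr))
  Xtr <- feature_matrix(train, columns)
  Xte <- feature_matrix(test, columns)
  sc <- scale_train(Xtr)
  Xtr_s <- sc$X
  Xte_s <- sweep(sweep(Xte, 2, sc$center), 2, sc$scale, "/")

  fit_predict <- switch(model_kind,
    BP = function() {
      Ytr <- one_hot(ytr)
      net <- withr::with_seed(as.integer(seed), {
        nnet::nnet(Xtr_s, Ytr,
          size = 16, softmax = TRUE, maxit = 500,
          trace = FALSE, MaxNWts = 5000
        )
      })
      list(
        train = factor(stats::predict(net, Xtr_s, type = "class"), levels = levels(ytr)),
        test = factor(stats::predict(net, Xte_s, type = "class"), levels = levels(ytr))
      )
    },
    SVM = function() {
      fit <- withr::with_seed(as.integer(seed), {
        e1071::svm(Xtr_s, ytr, kernel = "radial", scale = FALSE)
      })
      list(
        train = stats::predict(fit, Xtr_s),
        test = stats::predict(fit, Xte_s)
      )
    },
    RF = function() {
      fit <- withr::with_seed(as.integer(seed), {
        randomForest::randomForest(Xtr_s, ytr, ntree = 500)
      })
      list(
        train = stats::predict(fit, Xtr_s),
        test = stats::predict(fit, Xte_s)
      )
    },
    DBN = function() {
      fit <- withr::with_seed(as.integer(seed), {
        dbn_fit(Xtr, ytr, hidden = c(64L, 32L))
      })
      list(
        train = dbn_predict(fit, Xtr),
        test = dbn_predict(fit, Xte)
      )
    }
  )
  pred <- fit_predict()
  confusion <- table(true = yte, predicted = pred$test)
  structure(
    list(
      model_kind = model_kind, seed = as.integer(seed),
      train_accuracy = 100 * mean(pred$train == ytr),
      test_accuracy = 100 * mean(pred$test == yte),
      confusion = unclass(confusion),
      n_train = nrow(train), n_test = nrow(test)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s (seed %d): train %.2f%%, test %.2f%% (n = %d/%d)\n",
    x$model_kind, x$seed, x$train_accuracy, x$test_accuracy, x$n_train, x$n_test
  ))
  print(x$confusion)
  invisible(x)
}

#' Evaluate all four model families on one split
#'
#' @param split a [stratified_split()] result.
#' @param seed RNG seed shared by the learners.
#' @param label_col,columns as in [train_eval()].
#' @return A named list of [train_eval()] reports (BP, SVM, DBN, RF).
#' @export
train_eval_all <- function(split, seed = 42, label_col = "label", columns = NULL) {
  kinds <- c("BP", "SVM", "DBN", "RF")
  rlang::set_names(
    purrr::map(
      kinds,
      function(k) train_eval(k, split$train, split$test, seed, label_col, columns)
    ),
    kinds
  )
}

#' Compare raw-feature and fire-ice classification accuracy
#'
#' Per-model test-accuracy deltas (fire-ice minus raw). Both report sets
#' must come from the same samples and split seed.
#'
#' @param raw_reports,fireice_reports lists of [train_eval()] reports
#'   (as from [train_eval_all()]) for the raw 31-feature table and the
#'   fused 2-feature table.
#' @return A tibble: `model_kind`, `raw_test_accuracy`,
#'   `fireice_test_accuracy`, `delta` (percentage points).
#' @export
compare_matrices <- function(raw_reports, fireice_reports) {
  kr <- purrr::map_chr(raw_reports, "model_kind")
  kf <- purrr::map_chr(fireice_reports, "model_kind")
  if (!identical(sort(kr), sort(kf))) {
    rlang::abort("Report sets cover different model kinds.")
  }
  fireice_reports <- fireice_reports[match(kr, kf)]
  same_split <- purrr::map2_lgl(raw_reports, fireice_reports, function(a, b) {
    a$seed == b$seed && a$n_train == b$n_train && a$n_test == b$n_test
  })
  if (!all(same_split)) {
    rlang::abort("Reports were computed on different splits (seed or sizes differ).")
  }
  tibble::tibble(
    model_kind = kr,
    raw_test_accuracy = purrr::map_dbl(raw_reports, "test_accuracy"),
    fireice_test_accuracy = purrr::map_dbl(fireice_reports, "test_accuracy"),
    delta = .data$fireice_test_accuracy - .data$raw_test_accuracy
  )
}

# ---- Deep belief network --------------------------------------------------
# Two stacked binary RBMs pretrained with contrastive divergence (CD-1)
# on min-max scaled inputs, then a softmax output layer with full
# backpropagation fine-tuning. Small and CPU-friendly by design.

sigmoid <- function(x) 1 / (1 + exp(-x))

rbm_train <- function(V, n_hidden, epochs = 60, lr = 0.1, batch = 10) {
  n <- nrow(V)
  v <- ncol(V)
  W <- matrix(stats::rnorm(v * n_hidden, sd = 0.1), v, n_hidden)
  bv <- rep(0, v)
  bh <- rep(0, n_hidden)
  for (e in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1, n)]
      v0 <- V[idx, , drop = FALSE]
      h0 <- sigmoid(sweep(v0 %*% W, 2, bh, "+"))
      hs <- matrix(stats::rbinom(length(h0), 1, h0), nrow(h0))
      v1 <- sigmoid(sweep(hs %*% t(W), 2, bv, "+"))
      h1 <- sigmoid(sweep(v1 %*% W, 2, bh, "+"))
      m <- length(idx)
      W <- W + lr * (crossprod(v0, h0) - crossprod(v1, h1)) / m
      bv <- bv + lr * colMeans(v0 - v1)
      bh <- bh + lr * colMeans(h0 - h1)
    }
  }
  list(W = W, bv = bv, bh = bh)
}

dbn_fit <- function(X, y, hidden = c(64L, 32L), cd_epochs = 60,
                    ft_epochs = 300, ft_lr = 0.5) {
  # min-max scale with train statistics
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  rng <- pmax(maxs - mins, 1e-12)
  V <- sweep(sweep(X, 2, mins), 2, rng, "/")
  r1 <- rbm_train(V, hidden[1], epochs = cd_epochs)
  H1 <- sigmoid(sweep(V %*% r1$W, 2, r1$bh, "+"))
  r2 <- rbm_train(H1, hidden[2], epochs = cd_epochs)
  y <- as.factor(y)
  k <- nlevels(y)
  Y <- one_hot(y)
  W1 <- r1$W
  b1 <- r1$bh
  W2 <- r2$W
  b2 <- r2$bh
  W3 <- matrix(stats::rnorm(hidden[2] * k, sd = 0.1), hidden[2], k)
  b3 <- rep(0, k)
  n <- nrow(V)
  for (e in seq_len(ft_epochs)) {
    A1 <- sigmoid(sweep(V %*% W1, 2, b1, "+"))
    A2 <- sigmoid(sweep(A1 %*% W2, 2, b2, "+"))
    Z <- sweep(A2 %*% W3, 2, b3, "+")
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    d3 <- (P - Y) / n
    d2 <- (d3 %*% t(W3)) * A2 * (1 - A2)
    d1 <- (d2 %*% t(W2)) * A1 * (1 - A1)
    W3 <- W3 - ft_lr * crossprod(A2, d3)
    b3 <- b3 - ft_lr * colSums(d3)
    W2 <- W2 - ft_lr * crossprod(A1, d2)
    b2 <- b2 - ft_lr * colSums(d2)
    W1 <- W1 - ft_lr * crossprod(V, d1)
    b1 <- b1 - ft_lr * colSums(d1)
  }
  list(
    mins = mins, rng = rng, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
    W3 = W3, b3 = b3, classes = levels(y)
  )
}

dbn_predict <- function(fit, X) {
  V <- sweep(sweep(X, 2, fit$mins), 2, fit$rng, "/")
  V <- pmin(pmax(V, 0), 1)
  A1 <- sigmoid(sweep(V %*% fit$W1, 2, fit$b1, "+"))
  A2 <- sigmoid(sweep(A1 %*% fit$W2, 2, fit$b2, "+"))
  Z <- sweep(A2 %*% fit$W3, 2, fit$b3, "+")
  factor(fit$classes[max.col(Z)], levels = fit$classes)
}
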