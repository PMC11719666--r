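#' Principal component analysis of a feature table
#'
#' Autoscaled (mean-centred, unit-variance) PCA via the singular value
#' decomposition, with the explained-variance percentages of *all*
#' `min(n - 1, p)` components retained so that their total is 100.
#'
#' @param data a feature tibble (feature columns are selected with the
#'   package's canonical column rules) or a numeric matrix.
#' @param ncomp number of components to keep in the score matrix.
#' @param autoscale scale columns to unit variance (default TRUE);
#'   columns with zero variance raise an error naming the column.
#' @param columns optional explicit feature column names.
#' @return An object of class `seed_pca`: `scores` (n x ncomp),
#'   `loadings` (p x ncomp, orthonormal columns), `explained_pct`
#'   (the kept components), `explained_pct_full` (all components),
#'   `center`, `scale`, `labels`.
#' @export
run_pca <- function(data, ncomp = 3, autoscale = TRUE, columns = NULL) {
  X <- if (is.matrix(data)) data else feature_matrix(data, columns)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2 || p < 1) rlang::abort("PCA needs n >= 2 samples and p >= 1 features.")
  ncomp <- min(ncomp, n - 1, p)
  if (autoscale) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      rlang::abort(sprintf(
        "Zero-variance column(s) under autoscaling: %s",
        paste(colnames(X)[sds == 0], collapse = ", ")
      ))
    }
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = autoscale)
  ev <- fit$sdev^2
  ev <- ev[seq_len(min(n - 1, p))] # numerically-zero trailing dims excluded
  pct <- 100 * ev / sum(ev)
  labels <- if (!is.matrix(data) && "label" %in% names(data)) data$label else NULL
  structure(
    list(
      scores = fit$x[, seq_len(ncomp), drop = FALSE],
      loadings = fit$rotation[, seq_len(ncomp), drop = FALSE],
      explained_pct = pct[seq_len(ncomp)],
      explained_pct_full = pct,
      center = fit$center, scale = fit$scale,
      labels = labels, ncomp = ncomp
    ),
    class = "seed_pca"
  )
}

#' @export
print.seed_pca <- function(x, ...) {
  cat(sprintf(
    "<seed_pca> %d components: %s%% explained (cumulative %.1f%%)\n",
    x$ncomp, paste(sprintf("%.1f", x$explained_pct), collapse = "/"),
    sum(x$explained_pct)
  ))
  invisible(x)
}

# ---- PLS-DA ---------------------------------------------------------------

# NIPALS PLS2 on a scaled X and centred Y. Deflates both blocks; stops
# early (with the count actually fitted) when X is exhausted.
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500) {
  n <- nrow(X)
  p <- ncol(X)
  k <- ncol(Y)
  W <- matrix(0, p, 0)
  P <- matrix(0, p, 0)
  Q <- matrix(0, k, 0)
  TT <- matrix(0, n, 0)
  ssy <- numeric(0)
  Xa <- X
  Ya <- Y
  for (a in seq_len(ncomp)) {
    if (sum(Xa^2) < 1e-12 || sum(Ya^2) < 1e-12) break
    u <- Ya[, which.max(colSums(Ya^2))]
    t_old <- rep(Inf, n)
    w <- NULL
    tt <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xa, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      tt <- Xa %*% w
      q <- crossprod(Ya, tt) / sum(tt^2)
      u <- Ya %*% q / sum(q^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), 1e-300) < tol) break
      t_old <- tt
    }
    if (is.null(tt) || sum(tt^2) < 1e-12) break
    pvec <- crossprod(Xa, tt) / sum(tt^2)
    qvec <- crossprod(Ya, tt) / sum(tt^2)
    ss_before <- sum(Ya^2)
    Xa <- Xa - tt %*% t(pvec)
    Ya <- Ya - tt %*% t(qvec)
    ssy <- c(ssy, ss_before - sum(Ya^2))
    W <- cbind(W, w)
    P <- cbind(P, pvec)
    Q <- cbind(Q, qvec)
    TT <- cbind(TT, tt)
  }
  list(W = W, P = P, Q = Q, TT = TT, SSY = ssy, Y_res = Ya)
}

scale_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    rlang::abort(sprintf(
      "Zero-variance column(s) under autoscaling: %s",
      paste(colnames(X)[scl == 0], collapse = ", ")
    ))
  }
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

one_hot <- function(f) {
  f <- as.factor(f)
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  Y
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 on the autoscaled (unit-variance) feature matrix against
#' the centred one-hot class matrix, with deflation of both blocks.
#' Class prediction is the argmax of the predicted dummy scores. `Q2` is
#' estimated by stratified 7-fold cross-validation (PRESS over total SS,
#' with scaling refit inside each training fold). Requesting more
#' components than the data support truncates with a warning.
#'
#' @param data a feature tibble (with a label column) or numeric matrix.
#' @param labels class labels; taken from `data$label` when omitted.
#' @param ncomp number of components (default 3).
#' @param columns optional explicit feature columns.
#' @param cv_folds folds for Q2 (default 7); `cv_folds = 0` skips CV.
#' @param cv_seed RNG seed for the fold assignment.
#' @return An object of class `plsda` with scores, normalized weight
#'   vectors, loadings, per-component explained Y sums of squares
#'   (`SSY`), `R2Y`, `Q2`, per-feature `vip`, and the training-set
#'   confusion and accuracy.
#' @export
plsda_fit <- function(data, labels = NULL, ncomp = 3, columns = NULL,
                      cv_folds = 7, cv_seed = 7) {
  X <- if (is.matrix(data)) data else feature_matrix(data, columns)
  if (is.null(labels)) {
    if (!is.matrix(data) && "label" %in% names(data)) {
      labels <- data$label
    } else {
      rlang::abort("`labels` are required (no label column found).")
    }
  }
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) rlang::abort("PLS-DA needs at least 2 classes.")
  if (any(table(labels) < 2)) rlang::abort("Every class needs at least 2 members.")
  sc <- scale_train(X)
  Y <- one_hot(labels)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  max_rank <- min(nrow(X) - 1, ncol(X))
  if (ncomp > max_rank) {
    rlang::warn(sprintf("ncomp = %d exceeds the data rank; truncated to %d.", ncomp, max_rank))
    ncomp <- max_rank
  }
  fit <- nipals_pls2(sc$X, Yc, ncomp)
  if (ncol(fit$W) == 0) {
    rlang::abort("No PLS component could be extracted (X carries no usable variance).")
  }
  if (ncol(fit$W) < ncomp) {
    rlang::warn(sprintf(
      "X exhausted after %d component(s); requested %d.", ncol(fit$W), ncomp
    ))
  }
  ncomp <- ncol(fit$W)
  ssy_tot <- sum(Yc^2)
  R2Y <- sum(fit$SSY) / ssy_tot
  vip <- vip_scores(fit$W, fit$SSY)
  names(vip) <- colnames(X)
  # training predictions via the regression coefficients
  B <- fit$W %*% solve(crossprod(fit$P, fit$W), t(fit$Q))
  Yhat <- sc$X %*% B + matrix(y_means, nrow(X), ncol(Y), byrow = TRUE)
  pred <- factor(colnames(Y)[max.col(Yhat)], levels = levels(labels))
  Q2 <- NA_real_
  if (cv_folds > 1) {
    Q2 <- plsda_q2(X, labels, ncomp, cv_folds, cv_seed)
  }
  structure(
    list(
      ncomp = ncomp, scores = fit$TT, weights = fit$W,
      x_loadings = fit$P, y_loadings = fit$Q, SSY = fit$SSY,
      R2Y = R2Y, Q2 = Q2, vip = vip, coef = B,
      center = sc$center, scale = sc$scale, y_means = y_means,
      classes = levels(labels), labels = labels,
      feature_names = colnames(X),
      train_pred = pred,
      train_accuracy = 100 * mean(pred == labels)
    ),
    class = "plsda"
  )
}

# VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a), with ||w_a|| = 1.
vip_scores <- function(W, SSY) {
  p <- nrow(W)
  w2 <- sweep(W^2, 2, colSums(W^2), "/")
  sqrt(p * as.numeric(w2 %*% SSY) / sum(SSY))
}

#' Variable importance in projection
#'
#' @param model a fitted [plsda_fit()] model.
#' @return A named numeric vector; the squared values average to 1
#'   (`sum(vip^2) = p`).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  model$vip
}

# Stratified fold ids: classes split as evenly as possible across folds.
stratified_folds <- function(labels, k, seed) {
  ids <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      ids[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  ids
}

plsda_q2 <- function(X, labels, ncomp, folds, seed) {
  Y <- one_hot(labels)
  fold_id <- stratified_folds(labels, folds, seed)
  press <- 0
  ss <- 0
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    te <- !tr
    if (length(unique(labels[tr])) < nlevels(labels)) next
    sc <- scale_train(X[tr, , drop = FALSE])
    ym <- colMeans(Y[tr, , drop = FALSE])
    Yc <- sweep(Y[tr, , drop = FALSE], 2, ym)
    fit <- nipals_pls2(sc$X, Yc, ncomp)
    if (ncol(fit$W) == 0) next
    B <- fit$W %*% solve(crossprod(fit$P, fit$W), t(fit$Q))
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, sc$center), 2, sc$scale, "/")
    Yhat <- Xte %*% B + matrix(ym, sum(te), ncol(Y), byrow = TRUE)
    press <- press + sum((Y[te, , drop = FALSE] - Yhat)^2)
    ss <- ss + sum(sweep(Y[te, , drop = FALSE], 2, ym)^2)
  }
  1 - press / ss
}

#' Predict classes from a PLS-DA model
#'
#' @param object a fitted [plsda_fit()] model.
#' @param newdata feature tibble or matrix with the model's features.
#' @param ... unused.
#' @return A tibble with the predicted dummy scores and `class`.
#' @export
predict.plsda <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata, object$feature_names)
  X <- X[, object$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  Yhat <- Xs %*% object$coef +
    matrix(object$y_means, nrow(X), length(object$classes), byrow = TRUE)
  colnames(Yhat) <- object$classes
  out <- tibble::as_tibble(Yhat)
  out$class <- factor(object$classes[max.col(Yhat)], levels = object$classes)
  out
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf(
    "<plsda> %d classes, %d component(s): R2Y = %.3f, Q2 = %.3f, train acc = %.1f%%\n",
    length(x$classes), x$ncomp, x$R2Y, x$Q2, x$train_accuracy
  ))
  invisible(x)
}

#' Permutation test of a PLS-DA model
#'
#' Refits the model `nperm` times with randomly permuted class labels
#' and records, per permutation, the correlation of the permuted with
#' the original (centred one-hot) labels, `R2Y` and `Q2`. The empirical
#' p-value is `(#{permuted Q2 >= original Q2} + 1) / (nperm + 1)`.
#'
#' @param data feature tibble or matrix.
#' @param labels class labels (default `data$label`).
#' @param ncomp components, as in [plsda_fit()].
#' @param nperm number of permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @param columns optional explicit feature columns.
#' @param cv_folds,cv_seed passed to [plsda_fit()].
#' @return An object of class `permutation_test`: `results` (a tibble of
#'   `nperm + 1` rows; the first is the unpermuted model with label
#'   correlation 1), `p_value`, `nperm`.
#' @export
permutation_test <- function(data, labels = NULL, ncomp = 2, nperm = 200,
                             seed = 1, columns = NULL, cv_folds = 7, cv_seed = 7) {
  X <- if (is.matrix(data)) data else feature_matrix(data, columns)
  if (is.null(labels)) labels <- data$label
  labels <- as.factor(labels)
  ref <- plsda_fit(X, labels, ncomp, cv_folds = cv_folds, cv_seed = cv_seed)
  Y0 <- scale(one_hot(labels), scale = FALSE)
  perms <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(nperm), function(i) sample(seq_along(labels)))
  })
  rows <- purrr::map(perms, function(ord) {
    lp <- labels[ord]
    fit <- suppressWarnings(
      plsda_fit(X, lp, ncomp, cv_folds = cv_folds, cv_seed = cv_seed)
    )
    Yp <- scale(one_hot(lp), scale = FALSE)
    tibble::tibble(
      label_correlation = abs(stats::cor(as.vector(Yp), as.vector(Y0))),
      R2Y = fit$R2Y, Q2 = fit$Q2
    )
  })
  results <- dplyr::bind_rows(
    tibble::tibble(label_correlation = 1, R2Y = ref$R2Y, Q2 = ref$Q2, permutation = 0L),
    dplyr::mutate(dplyr::bind_rows(rows), permutation = dplyr::row_number())
  )
  p_value <- (sum(results$Q2[-1] >= ref$Q2) + 1) / (nperm + 1)
  structure(
    list(results = results, p_value = p_value, nperm = nperm, model = ref),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "<permutation_test> %d permutations: original Q2 = %.3f, empirical p = %.4g\n",
    x$nperm, x$model$Q2, x$p_value
  ))
  invisible(x)
}

#' Per-feature one-way ANOVA p-values
#'
#' Classic equal-variance one-way ANOVA F-test per feature column
#' (via `stats::oneway.test(var.equal = TRUE)`). Features with zero
#' between-group and zero within-group variance get `p = 1`.
#'
#' @param data feature tibble or matrix.
#' @param labels group labels (default `data$label`).
#' @param columns optional explicit feature columns.
#' @return A tibble: `feature`, `f_statistic`, `p_value`.
#' @export
anova_pvalues <- function(data, labels = NULL, columns = NULL) {
  X <- if (is.matrix(data)) data else feature_matrix(data, columns)
  if (is.null(labels)) labels <- data$label
  g <- as.factor(labels)
  if (nlevels(g) < 2) rlang::abort("ANOVA needs at least 2 groups.")
  if (any(table(g) < 2)) rlang::abort("Every group needs at least 2 members.")
  res <- purrr::map(colnames(X), function(cn) {
    x <- X[, cn]
    ft <- tryCatch(
      stats::oneway.test(x ~ g, var.equal = TRUE),
      error = function(e) NULL
    )
    f <- if (is.null(ft)) NaN else unname(ft$statistic)
    p <- if (is.null(ft)) NaN else ft$p.value
    if (!is.finite(p)) { # degenerate: no variance anywhere
      f <- 0
      p <- 1
    }
    tibble::tibble(feature = cn, f_statistic = f, p_value = p)
  })
  dplyr::bind_rows(res)
}

#' Select marker features by the VIP and significance rule
#'
#' Keeps features with `vip > 1` and `p < 0.05` (strict inequalities).
#'
#' @param vip named numeric VIP vector (e.g. from [vip()]).
#' @param pvals numeric p-values, or the tibble from [anova_pvalues()].
#' @param names feature names; defaults to `names(vip)`.
#' @return A tibble of the selected features: `feature`, `vip`,
#'   `p_value`, ordered by decreasing VIP.
#' @export
select_markers <- function(vip, pvals, names = NULL) {
  if (is.data.frame(pvals)) {
    nm <- pvals$feature
    pv <- pvals$p_value
    if (!is.null(names(vip))) {
      vip <- vip[match(nm, names(vip))]
    }
    names <- nm
    pvals <- pv
  }
  if (is.null(names)) names <- names(vip)
  if (length(vip) != length(pvals) || length(vip) != length(names)) {
    rlang::abort("`vip`, `pvals` and `names` must have equal lengths.")
  }
  out <- tibble::tibble(feature = names, vip = unname(vip), p_value = pvals)
  dplyr::arrange(
    dplyr::filter(out, .data$vip > 1, .data$p_value < 0.05),
    dplyr::desc(.data$vip)
  )
}
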