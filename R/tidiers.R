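#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PCA result
#'
#' @param x a [run_pca()] result.
#' @param matrix `"scores"` (one row per sample), `"loadings"` (one row
#'   per feature) or `"eigenvalues"` (one row per component).
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.seed_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    out <- tibble::as_tibble(x$scores, .name_repair = "minimal")
    names(out) <- paste0("PC", seq_len(ncol(out)))
    out <- tibble::add_column(out,
      sample_id = rownames(x$scores) %||% as.character(seq_len(nrow(out))),
      label = x$labels %||% NA_character_, .before = 1
    )
    return(out)
  }
  if (matrix == "loadings") {
    out <- tibble::as_tibble(x$loadings, .name_repair = "minimal")
    names(out) <- paste0("PC", seq_len(ncol(out)))
    return(tibble::add_column(out,
      feature = rownames(x$loadings) %||% as.character(seq_len(nrow(out))),
      .before = 1
    ))
  }
  tibble::tibble(
    component = seq_along(x$explained_pct_full),
    explained_pct = x$explained_pct_full,
    cumulative_pct = cumsum(x$explained_pct_full)
  )
}

#' @rdname tidy.seed_pca
#' @export
glance.seed_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores), ncomp = x$ncomp,
    explained_pct = sum(x$explained_pct),
    total_components = length(x$explained_pct_full)
  )
}

#' Tidy a PLS-DA model
#'
#' One row per feature with its VIP score and per-component weights.
#'
#' @param x a [plsda_fit()] model.
#' @param ... unused.
#' @return A tibble: `feature`, `vip`, `w1` ... `w<ncomp>`.
#' @export
tidy.plsda <- function(x, ...) {
  W <- x$weights
  colnames(W) <- paste0("w", seq_len(ncol(W)))
  dplyr::bind_cols(
    tibble::tibble(feature = x$feature_names, vip = unname(x$vip)),
    tibble::as_tibble(W)
  )
}

#' @rdname tidy.plsda
#' @export
glance.plsda <- function(x, ...) {
  tibble::tibble(
    ncomp = x$ncomp, R2Y = x$R2Y, Q2 = x$Q2,
    train_accuracy = x$train_accuracy,
    n = length(x$labels), n_classes = length(x$classes)
  )
}

#' Tidy a permutation test
#'
#' @param x a [permutation_test()] result.
#' @param ... unused.
#' @return The `nperm + 1` row results tibble (`permutation`,
#'   `label_correlation`, `R2Y`, `Q2`); permutation 0 is the original
#'   model.
#' @export
tidy.permutation_test <- function(x, ...) {
  dplyr::relocate(x$results, "permutation")
}

#' @rdname tidy.permutation_test
#' @export
glance.permutation_test <- function(x, ...) {
  tibble::tibble(
    nperm = x$nperm, p_value = x$p_value,
    R2Y = x$model$R2Y, Q2 = x$model$Q2
  )
}

#' Tidy a classifier evaluation report
#'
#' @param x a [train_eval()] report.
#' @param ... unused.
#' @return The confusion matrix in long form: `true`, `predicted`, `n`.
#' @export
tidy.eval_report <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  names(df) <- c("true", "predicted", "n")
  tibble::as_tibble(df)
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    model_kind = x$model_kind, seed = x$seed,
    train_accuracy = x$train_accuracy, test_accuracy = x$test_accuracy,
    n_train = x$n_train, n_test = x$n_test
  )
}
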