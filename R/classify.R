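#' SVM kernel presets
#'
#' The four kernels of the severity-classification experiment: `linear`,
#' `quadratic` (polynomial degree 2), `cubic` (polynomial degree 3) and
#' `medium_gaussian` (radial basis with length scale `sqrt(k)`, i.e.
#' `gamma = 1/k` for `k` features — the conventional "medium" preset).
#'
#' @return Character vector of the four preset names.
#' @export
svm_kernels <- function() c("linear", "quadratic", "cubic", "medium_gaussian")

svm_args <- function(kernel, k_features, cost = 1) {
  base <- list(type = "C-classification", cost = cost, scale = TRUE)
  extra <- switch(kernel,
    linear = list(kernel = "linear"),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = 1, coef0 = 1),
    cubic = list(kernel = "polynomial", degree = 3, gamma = 1, coef0 = 1),
    medium_gaussian = list(kernel = "radial", gamma = 1 / k_features),
    stop("unknown kernel preset: ", kernel))
  c(base, extra)
}

# Seeded stratified fold assignment: shuffle within each group, deal
# round-robin so fold sizes are balanced per group.
stratified_folds <- function(labels, folds, seed) {
  g <- factor(labels)
  assign <- integer(length(g))
  with_seed(seed, {
    for (lev in levels(g)) {
      idx <- sample(which(g == lev))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated SVM classification accuracy
#'
#' Stratified k-fold cross-validation of a two-group SVM (unit box
#' constraint) on a reduced feature block. Features are standardized inside
#' each training fold only (the SVM's scaling statistics come from the
#' training data it is fit on). Deterministic given `seed`.
#'
#' @param fm A `feature_matrix` (typically PCA scores from [pca_reduce()]).
#' @param kernel One of [svm_kernels()].
#' @param folds Number of folds; must not exceed the smaller group size.
#' @param seed Fold-assignment seed.
#' @param cost SVM box constraint.
#' @return A `cv_report`: kernel, `k_features`, `fold` assignment,
#'   `fold_accuracy` (%), `accuracy` (% of all subjects correctly
#'   classified, a multiple of 100/N).
#' @export
cv_accuracy <- function(fm, kernel = "medium_gaussian", folds = 5, seed = 1,
                        cost = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  kernel <- match.arg(kernel, svm_kernels())
  X <- fm$values
  y <- droplevels(factor(fm$labels))
  if (nlevels(y) != 2) stop("both groups must be present")
  if (folds < 2) stop("need at least 2 folds")
  if (folds > min(table(y)))
    stop("folds (", folds, ") exceed the smaller group size (",
         min(table(y)), "); use fewer folds")
  assign <- stratified_folds(y, folds, seed)
  correct <- logical(nrow(X))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- assign != f; te <- !tr
    if (nlevels(droplevels(y[tr])) < 2)
      stop("degenerate fold ", f, ": training data single-class; ",
           "use fewer folds")
    args <- c(list(x = X[tr, , drop = FALSE], y = y[tr]),
              svm_args(kernel, ncol(X), cost))
    fitted <- do.call(e1071::svm, args)
    pred <- stats::predict(fitted, X[te, , drop = FALSE])
    correct[te] <- pred == y[te]
    fold_acc[f] <- 100 * mean(pred == y[te])
  }
  structure(list(kernel = kernel, k_features = ncol(X), folds = assign,
                 fold_accuracy = fold_acc,
                 accuracy = 100 * sum(correct) / nrow(X)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s kernel, k = %d, accuracy = %.1f%%\n",
              x$kernel, x$k_features, x$accuracy))
  invisible(x)
}

# Leakage-safe CV: PCA is refit on each training fold and the held-out
# subjects are projected on the training loadings.
cv_accuracy_pca_in_cv <- function(fm, k, kernel, folds, seed, cost = 1) {
  X <- fm$values
  y <- droplevels(factor(fm$labels))
  assign <- stratified_folds(y, folds, seed)
  correct <- logical(nrow(X))
  for (f in seq_len(folds)) {
    tr <- assign != f; te <- !tr
    red <- pca_reduce(new_feature_matrix(X[tr, , drop = FALSE], y[tr],
                                         fm$roi, fm$emotion), k)
    Ztr <- red$reduced$values
    Zte <- sweep(X[te, , drop = FALSE], 2, red$model$means) %*%
      red$model$loadings
    args <- c(list(x = Ztr, y = y[tr]), svm_args(kernel, k, cost))
    fitted <- do.call(e1071::svm, args)
    correct[te] <- stats::predict(fitted, Zte) == y[te]
  }
  structure(list(kernel = kernel, k_features = k, folds = assign,
                 fold_accuracy = NULL,
                 accuracy = 100 * sum(correct) / nrow(X)),
            class = "cv_report")
}

#' Accuracy grid over kernels and retained-component counts
#'
#' Re-fits the PCA for each `k` in `k_values` and cross-validates every
#' kernel preset, mirroring the kernel x feature-count accuracy table of the
#' severity-classification experiment (kernels as rows, `k` as columns). The
#' same seed is used for every cell so all cells share fold splits.
#'
#' @param fm An unreduced `feature_matrix` block (n x 48).
#' @param k_values Retained-component counts (default 8:12).
#' @param kernels Kernel presets to sweep.
#' @param folds,seed,cost Passed to [cv_accuracy()].
#' @param pca_in_cv If `TRUE`, the PCA is refit inside each training fold
#'   (leakage-safe, the methodologically preferred option); if `FALSE`
#'   (default) the PCA is fit once on the full block before CV, mirroring
#'   the sequential reduce-then-classify protocol.
#' @return Data frame with columns `kernel`, `k`, `accuracy` (%).
#' @export
sweep_feature_counts <- function(fm, k_values = 8:12,
                                 kernels = svm_kernels(), folds = 5,
                                 seed = 1, cost = 1, pca_in_cv = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$values)
  if (max(k_values) > min(n - 1, ncol(fm$values)))
    stop("max(k_values) exceeds min(n - 1, p)")
  rows <- list()
  for (k in k_values) {
    red <- if (pca_in_cv) NULL else pca_reduce(fm, k)$reduced
    for (kern in kernels) {
      cvr <- if (pca_in_cv)
        cv_accuracy_pca_in_cv(fm, k, kern, folds, seed, cost)
      else
        cv_accuracy(red, kern, folds, seed, cost)
      rows[[length(rows) + 1]] <-
        data.frame(kernel = kern, k = k, accuracy = cvr$accuracy,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
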