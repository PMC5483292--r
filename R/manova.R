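#' Principal-component reduction of a feature block
#'
#' Columns are centered (not scaled: all features share degrees C) and
#' projected on the top `k` principal axes, reducing each subject's 48
#' temperature-change features to `k` (default 9) scores. Component signs
#' follow the convention that each loading's largest-magnitude entry is
#' positive, for reproducibility.
#'
#' @param fm A `feature_matrix` (see [cohort_feature_matrix()]).
#' @param k Number of retained components; must satisfy
#'   `k <= min(n - 1, p)`.
#' @return List: `model` (`means`, `loadings` p x k orthonormal,
#'   `explained_variance` fractions) and `reduced` (a `feature_matrix` of
#'   n x k scores with labels preserved).
#' @export
pca_reduce <- function(fm, k = 9) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$values
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("PCA needs at least 2 subjects")
  if (k < 1 || k > min(n - 1, p))
    stop("k = ", k, " exceeds min(n - 1, p) = ", min(n - 1, p))
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  kk <- min(k, ncol(pr$rotation))
  load <- pr$rotation[, seq_len(kk), drop = FALSE]
  scores <- pr$x[, seq_len(kk), drop = FALSE]
  if (kk < k) {  # rank-deficient input: pad with zero-variance components
    load <- cbind(load, matrix(0, p, k - kk))
    scores <- cbind(scores, matrix(0, n, k - kk))
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(k))
  tot <- sum(pr$sdev^2)
  evar <- if (tot > 0) (pr$sdev^2 / tot) else rep(0, length(pr$sdev))
  evar <- c(evar, rep(0, max(0, k - length(evar))))[seq_len(k)]
  model <- list(means = pr$center, loadings = load,
                explained_variance = evar)
  list(model = model,
       reduced = new_feature_matrix(scores, fm$labels, fm$roi, fm$emotion))
}

#' Two-group MANOVA via Wilks' lambda
#'
#' Tests whether the multivariate feature means differ between the two
#' severity groups. Wilks' statistic is `Lambda = det(E) / det(E + H)` with
#' `E` the within-group and `H` the between-group SSCP matrix; for two
#' groups the transform `F = ((1 - Lambda) / Lambda) * ((N - k - 1) / k)` is
#' exactly F-distributed on `(k, N - k - 1)` degrees of freedom under the
#' null (it equals the Hotelling T-squared F).
#'
#' @param fm A `feature_matrix` with two groups of >= 2 subjects each.
#' @return A `manova_result`: `wilks_lambda`, `f_value`, `df1`, `df2`,
#'   `p_value`.
#' @export
manova_wilks <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$values
  g <- droplevels(factor(fm$labels))
  if (nlevels(g) != 2)
    stop("exactly two groups are required (got ", nlevels(g), ")")
  if (any(table(g) < 2)) stop("each group needs at least 2 subjects")
  N <- nrow(X); k <- ncol(X)
  if (N - k - 1 < 1)
    stop("too few subjects for k = ", k, " features (need N >= k + 2)")
  grand <- colMeans(X)
  E <- matrix(0, k, k); H <- matrix(0, k, k)
  for (lev in levels(g)) {
    Xg <- X[g == lev, , drop = FALSE]
    mg <- colMeans(Xg)
    C <- sweep(Xg, 2, mg)
    E <- E + crossprod(C)
    H <- H + nrow(Xg) * tcrossprod(mg - grand)
  }
  chE <- tryCatch(chol(E), error = function(e) NULL)
  if (is.null(chE))
    stop("within-group SSCP matrix is singular; reduce k")
  chT <- chol(E + H)
  lambda <- exp(2 * sum(log(diag(chE))) - 2 * sum(log(diag(chT))))
  lambda <- min(lambda, 1)
  f_value <- (1 - lambda) / lambda * (N - k - 1) / k
  structure(list(wilks_lambda = lambda, f_value = f_value,
                 df1 = as.integer(k), df2 = as.integer(N - k - 1),
                 p_value = stats::pf(f_value, k, N - k - 1,
                                     lower.tail = FALSE)),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("Wilks' lambda = %.4f, F(%d, %d) = %.3f, p = %.4g\n",
              x$wilks_lambda, x$df1, x$df2, x$f_value, x$p_value))
  invisible(x)
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' MANOVA results table over all ROI x emotion blocks
#'
#' Reduces every block to `k` principal components and tests the group
#' difference per cell, emitting F, p and significance stars (0.05 / 0.01 /
#' 0.001) in a 5-ROI x 4-emotion layout (three evoked emotions plus the
#' REST "no stimulus" block).
#'
#' @param blocks Named block list from [cohort_feature_matrix()].
#' @param k Retained components per block.
#' @param adjust `"none"` (raw p-values, the default reporting convention
#'   here) or `"bonferroni"`.
#' @param on_error `"stop"` propagates per-cell failures (e.g. singular
#'   within-group SSCP); `"na"` records them as `NA` cells with a note.
#' @return Data frame: roi, emotion, wilks_lambda, f_value, df1, df2,
#'   p_value, stars (and `note` when `on_error = "na"`).
#' @export
table2_analysis <- function(blocks, k = 9, adjust = c("none", "bonferroni"),
                            on_error = c("stop", "na")) {
  adjust <- match.arg(adjust)
  on_error <- match.arg(on_error)
  emotions <- emotion_levels()
  rows <- list()
  for (roi in .ROI_NAMES) {
    for (emo in emotions) {
      key <- paste(roi, emo, sep = ".")
      if (is.null(blocks[[key]]))
        stop("missing feature block for cell ", roi, " x ", emo)
      cell <- tryCatch({
        red <- pca_reduce(blocks[[key]], k)$reduced
        r <- manova_wilks(red)
        data.frame(roi = roi, emotion = emo, wilks_lambda = r$wilks_lambda,
                   f_value = r$f_value, df1 = r$df1, df2 = r$df2,
                   p_value = r$p_value, note = "",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        if (on_error == "stop")
          stop("cell ", roi, " x ", emo, ": ", conditionMessage(e))
        data.frame(roi = roi, emotion = emo, wilks_lambda = NA_real_,
                   f_value = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                   p_value = NA_real_, note = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[key]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "bonferroni")
    out$p_value <- pmin(out$p_value * nrow(out), 1)
  out$stars <- p_stars(out$p_value)
  if (on_error == "stop") out$note <- NULL
  out
}
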