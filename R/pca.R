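#' Principal components of a genotype matrix
#'
#' Missing genotypes are imputed to the marker mean; markers are centred and
#' scaled (unit variance by default, or the drift scaling
#' `sqrt(2p(1-p))`), zero-variance markers dropped; components come from the
#' eigendecomposition of the individual-by-individual cross-product of the
#' standardized matrix. Each component is oriented so that its
#' largest-magnitude marker loading is positive, giving reproducible plots.
#'
#' With unit scaling, the eigenvalues (variances) across all components sum
#' to the number of retained markers.
#'
#' @param genotypes integer matrix of alt-allele counts (`NA` missing),
#'   normally the QC-passed matrix.
#' @param n_components number of components to return.
#' @param scaling `"unit"` (divide each centred marker by its standard
#'   deviation, the default) or `"drift"` (divide by `sqrt(2p(1-p))`).
#' @return object of class `pca_result`: `scores` (individuals x
#'   components), `explained` (variance fractions), `eigenvalues` (all
#'   positive eigenvalues), `n_markers_used`.
#' @export
run_pca <- function(genotypes, n_components = 2, scaling = c("unit", "drift")) {
  scaling <- match.arg(scaling)
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2)
  X <- genotypes
  storage.mode(X) <- "double"

  # mean imputation per marker
  mu <- colMeans(X, na.rm = TRUE)
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx)) X[na_idx] <- mu[na_idx[, 2]]

  X <- sweep(X, 2, colMeans(X))
  sc <- if (scaling == "unit") {
    apply(X, 2, stats::sd)
  } else {
    p <- mu / 2
    sqrt(2 * p * (1 - p))
  }
  keep <- !is.na(sc) & sc > 0
  X <- sweep(X[, keep, drop = FALSE], 2, sc[keep], "/")
  m <- ncol(X)
  if (m == 0) .stopf("no polymorphic markers left for PCA")

  n <- nrow(X)
  ee <- eigen(tcrossprod(X) / (n - 1), symmetric = TRUE)
  tol <- max(ee$values) * 1e-10
  pos <- ee$values > tol
  eigenvalues <- ee$values[pos]
  rank <- sum(pos)
  if (n_components > rank) {
    .warnf("n_components = %d exceeds rank %d; truncating", n_components, rank)
    n_components <- rank
  }

  scores <- ee$vectors[, seq_len(rank), drop = FALSE] %*%
    diag(sqrt(eigenvalues * (n - 1)), rank)
  # orient by the sign of the largest-magnitude marker loading
  for (j in seq_len(rank)) {
    loading <- crossprod(X, scores[, j])
    if (loading[which.max(abs(loading))] < 0) scores[, j] <- -scores[, j]
  }
  scores <- scores[, seq_len(n_components), drop = FALSE]
  dimnames(scores) <- list(rownames(genotypes),
                           paste0("PC", seq_len(n_components)))

  structure(list(scores = scores,
                 explained = eigenvalues / sum(eigenvalues),
                 eigenvalues = eigenvalues,
                 n_markers_used = m, scaling = scaling),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("PCA of %d individuals x %d markers (%s scaling)\n",
              nrow(x$scores), x$n_markers_used, x$scaling))
  cat(sprintf("  %s\n", paste(sprintf("PC%d: %.1f%%", seq_len(k),
                                      100 * x$explained[seq_len(k)]),
                              collapse = ", ")))
  invisible(x)
}

#' Join PCA scores with group labels for plotting
#'
#' Merges the per-individual scores with the fecundity group labels and
#' attaches 95% concentration-ellipse parameters per group (mean vector,
#' 2x2 covariance, chi-squared radius) as the `"ellipses"` attribute.
#'
#' @param pca a [run_pca()] result.
#' @param groups a [assign_groups()] result (ids must match the score rows).
#' @return data frame `id`, `PC1`, `PC2`, ..., `label`.
#' @export
group_overlay <- function(pca, groups) {
  ids <- rownames(pca$scores)
  asg <- groups$assignments
  if (!setequal(ids, asg$id))
    .stopf("individual ids in PCA scores and group assignment do not match")
  df <- data.frame(id = ids, pca$scores, stringsAsFactors = FALSE, row.names = NULL)
  df$label <- asg$label[match(df$id, asg$id)]

  ell <- NULL
  if (ncol(pca$scores) >= 2) {
    ell <- lapply(split(df, df$label), function(d) {
      S <- d[, c("PC1", "PC2")]
      list(center = colMeans(S),
           cov = if (nrow(S) > 2) stats::cov(S) else diag(2) * NA,
           radius = sqrt(stats::qchisq(0.95, df = 2)))
    })
  }
  attr(df, "ellipses") <- ell
  df
}

#' @export
plot.pca_result <- function(x, groups = NULL, ...) {
  if (ncol(x$scores) < 2) .stopf("need at least two components to plot")
  col <- "grey30"
  if (!is.null(groups)) {
    lab <- groups$assignments$label[match(rownames(x$scores),
                                          groups$assignments$id)]
    col <- ifelse(lab == "high", "dodgerblue3", "firebrick3")
  }
  graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = c("high", "low"), pch = 19,
                     col = c("dodgerblue3", "firebrick3"), bty = "n")
  invisible(x)
}
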