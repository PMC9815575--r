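# Conformational landscape: PCA on pair-distance feature matrices.

#' Fit a PCA model on a feature matrix
#'
#' Features are centered (not standardized; all features share the
#' Angstrom scale) and the sample covariance (N-1 scaling) is
#' eigen-decomposed. Eigenvector signs follow a deterministic
#' convention: the entry of largest magnitude in each component is
#' positive. Constant (zero-variance) columns are kept and reported.
#'
#' @param fm a [feature_matrix()], typically the combined two-system
#'   ensemble.
#' @param fitted_on label recording what was fitted (default
#'   "combined").
#' @return Object of class `pca_model`: `mean`, `rotation`
#'   (features x components), `eigenvalues`, `explained_ratio`,
#'   `labels`, `constant_features`.
#' @export
fit_pca <- function(fm, fitted_on = "combined") {
  X <- fm$values
  if (ncol(X) < 2) stop("PCA needs at least 2 features")
  if (nrow(X) <= ncol(X))
    warning("fewer frames than features; covariance is rank-deficient")
  mu <- colMeans(X)
  C <- cov(X)
  ee <- eigen(C, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  V <- ee$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  const <- fm$labels[apply(X, 2, function(col) all(col == col[1]))]
  if (length(const))
    message("constant feature column(s) retained: ",
            paste(const, collapse = ", "))
  structure(list(mean = mu, rotation = V, eigenvalues = lam,
                 explained_ratio = lam / sum(lam), labels = fm$labels,
                 constant_features = const, fitted_on = fitted_on),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model (", x$fitted_on, "): ", length(x$labels),
      " features; PC1+PC2 explain ",
      round(100 * sum(x$explained_ratio[1:2]), 1), "%\n", sep = "")
  invisible(x)
}

#' Project frames onto the leading principal components
#'
#' @param model a [pca_model][fit_pca()].
#' @param fm a [feature_matrix()] with the same labels.
#' @param n_components number of components (default 2).
#' @return frames x n_components matrix; frame provenance attached as
#'   attribute `info`.
#' @export
project_pca <- function(model, fm, n_components = 2) {
  if (!identical(fm$labels, model$labels))
    stop("feature labels do not match the fitted model")
  Xc <- sweep(fm$values, 2, model$mean)
  proj <- Xc %*% model$rotation[, seq_len(n_components), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(n_components))
  attr(proj, "info") <- fm$info
  proj
}

#' Rank features by their PC loadings
#'
#' Three rankings are reported: by |PC1|, by |PC2| and by the combined
#' score sqrt(PC1^2 + PC2^2).
#'
#' @param model a [pca_model][fit_pca()].
#' @param pcs the two components to report (default 1 and 2).
#' @param k number of top features per ranking.
#' @return list of three data.frames (`pc1`, `pc2`, `combined`), each
#'   with `label`, the loading(s) and the ranking score.
#' @export
top_loadings <- function(model, pcs = c(1, 2), k = 10) {
  if (k > length(model$labels)) stop("k exceeds the number of features")
  l1 <- model$rotation[, pcs[1]]
  l2 <- model$rotation[, pcs[2]]
  base <- data.frame(label = model$labels, pc1 = l1, pc2 = l2,
                     combined = sqrt(l1^2 + l2^2))
  take <- function(score) {
    out <- base[order(-score, base$label), , drop = FALSE]
    out <- head(out, k)
    rownames(out) <- NULL
    out
  }
  list(pc1 = take(abs(base$pc1)), pc2 = take(abs(base$pc2)),
       combined = take(base$combined))
}
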