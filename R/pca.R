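#' Principal component analysis of pixel spectra
#'
#' Column-mean-centered PCA via singular value decomposition, the
#' deterministic route.  With `X` the N x K spectra matrix, the model
#' decomposes the centered data into scores (N x A) and orthonormal loadings
#' (K x A); `scores %*% t(loadings)` plus the center reconstructs `X` up to
#' the energy of the discarded singular values.  For reproducibility each
#' component's sign is fixed so that the largest-magnitude element of its
#' loading is positive.
#'
#' @param X N x K numeric matrix (pixel spectra in rows).
#' @param A number of components to retain; at most `min(N, K)`.
#' @return An object of class `mfi_pca` with fields `center`, `loadings`
#'   (K x A), `scores` (N x A), `explained_variance` (variance of each score
#'   column, A-vector), `explained_fraction` and `total_variance`.
#' @seealso [pca_project()] to project new spectra, [pc_score_image()] for
#'   pixelwise score images.
#' @export
pca_fit <- function(X, A = min(dim(X))) {
  X <- as.matrix(X)
  N <- nrow(X); K <- ncol(X)
  if (N < 2L) stop("PCA needs at least 2 rows")
  if (A < 1L || A > min(N, K)) stop("A must be between 1 and min(N, K)")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  total_var <- sum(Xc^2) / (N - 1)
  if (total_var == 0) stop("degenerate input: all rows identical")
  sv <- svd(Xc, nu = A, nv = A)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(A)], A, A)
  for (a in seq_len(A)) {                  # deterministic sign convention
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  ev <- sv$d[seq_len(A)]^2 / (N - 1)
  structure(list(center = center, loadings = loadings, scores = scores,
                 explained_variance = ev,
                 explained_fraction = ev / total_var,
                 total_variance = total_var, all_singular_values = sv$d),
            class = "mfi_pca")
}

#' Project spectra onto a fitted PCA model
#'
#' Centers `X_new` with the training center and projects onto the loadings.
#' Projecting the training data reproduces the stored scores; projecting the
#' center itself gives a zero score vector.
#'
#' @param model an `mfi_pca` from [pca_fit()].
#' @param X_new matrix (or single spectrum) with the training band count.
#' @return Score matrix (rows x A).
#' @export
pca_project <- function(model, X_new) {
  X_new <- rbind(X_new)
  if (ncol(X_new) != length(model$center))
    stop("band count of new spectra does not match the fitted model")
  sweep(X_new, 2L, model$center) %*% model$loadings
}

#' @export
predict.mfi_pca <- function(object, newdata, ...) pca_project(object, newdata)

#' @export
print.mfi_pca <- function(x, ...) {
  A <- ncol(x$loadings)
  cat(sprintf("PCA model: %d band(s), %d component(s)\n", nrow(x$loadings), A))
  cat("  explained variance fraction:",
      paste(sprintf("PC%d=%.3f", seq_len(A), x$explained_fraction), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
plot.mfi_pca <- function(x, comps = c(2L, 3L), labels = NULL, ...) {
  if (max(comps) > ncol(x$scores)) stop("requested components not in model")
  s <- x$scores[, comps, drop = FALSE]
  col <- if (is.null(labels)) 1L else as.integer(factor(labels)) + 1L
  plot(s[, 1], s[, 2], col = col, pch = 20,
       xlab = sprintf("PC%d score", comps[1]),
       ylab = sprintf("PC%d score", comps[2]), ...)
  if (!is.null(labels))
    legend("topright", legend = levels(factor(labels)), pch = 20,
           col = seq_along(levels(factor(labels))) + 1L)
  invisible(x)
}

#' @export
summary.mfi_pca <- function(object, ...) {
  A <- ncol(object$loadings)
  data.frame(component = seq_len(A),
             variance = object$explained_variance,
             fraction = object$explained_fraction,
             cumulative = cumsum(object$explained_fraction))
}
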