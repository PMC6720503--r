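#' Partial least squares discriminant analysis
#'
#' PLS-DA regresses a dummy-coded class response on the spectra by partial
#' least squares and classifies from the continuous predictions.  Two
#' codings are supported: `"onehot"` (one 0/1 indicator column per class,
#' PLS2, class by arg-max — the three-class mode used for upper/bottom/skin
#' discrimination) and `"binary"` (exactly two classes coded 0/1 in a single
#' column, class by the 0.5 cut; the classical feces-versus-skin mode).
#'
#' Latent variables are extracted with the improved kernel PLS algorithm
#' (Dayal & MacGregor 1997), which is algebraically equivalent to NIPALS
#' PLS2 but deterministic, operating only on the K x K and K x C
#' cross-product matrices.  With `n_latent` equal to the rank of the
#' centered spectra the coefficients coincide with the multivariate
#' least-squares solution.  Preprocessing (see [prep_config()]) is fitted on
#' the training spectra and stored in the model so prediction applies the
#' identical transform.
#'
#' @param X N x K spectra matrix.
#' @param y class labels (character or factor), at least two classes with at
#'   least two samples each.
#' @param n_latent number of latent variables; at most `min(N - 1, K)`.
#' @param prep a [prep_config()]; default no preprocessing.
#' @param coding `"onehot"` or `"binary"`.
#' @return An object of class `mfi_plsda`; see Details.  `coef()` returns
#'   the coefficient matrix with an intercept row.
#' @export
plsda_fit <- function(X, y, n_latent = 3L, prep = prep_config("none"),
                      coding = c("onehot", "binary")) {
  coding <- match.arg(coding)
  X <- as.matrix(X)
  classes <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(as.character(y)))
  y <- as.character(y)
  if (length(classes) < 2L) stop("PLS-DA needs at least two classes")
  if (any(table(y) < 2L)) stop("every class needs at least two samples")
  if (coding == "binary" && length(classes) != 2L)
    stop("binary coding requires exactly two classes")
  if (n_latent > min(nrow(X) - 1L, ncol(X)))
    stop("n_latent exceeds min(N - 1, K)")

  pf <- prep_fit(X, prep)
  Xp <- prep_apply(pf, X)
  Y <- class_indicator(y, classes, coding)

  x_center <- colMeans(Xp)
  y_center <- colMeans(Y)
  Xc <- sweep(Xp, 2L, x_center)
  Yc <- sweep(Y, 2L, y_center)
  core <- kernel_pls(crossprod(Xc), crossprod(Xc, Yc), n_latent)
  colnames(core$B) <- colnames(Y)

  structure(list(beta = core$B, intercept = as.numeric(y_center - x_center %*% core$B),
                 classes = classes, coding = coding, n_latent = n_latent,
                 prep = pf, x_center = x_center, y_center = y_center,
                 R = core$R, P = core$P, Q = core$Q,
                 n = nrow(X)),
            class = "mfi_plsda")
}

# 0/1 response coding
class_indicator <- function(y, classes, coding) {
  if (coding == "binary") {
    Y <- matrix(as.numeric(y == classes[2L]), ncol = 1L,
                dimnames = list(NULL, classes[2L]))
  } else {
    Y <- sapply(classes, function(cl) as.numeric(y == cl))
    dimnames(Y) <- list(NULL, classes)
  }
  Y
}

# Improved kernel PLS (Dayal & MacGregor, algorithm 1) on centered
# cross-products XtX (K x K) and XtY (K x C).  Returns the K x C coefficient
# matrix and the weight/loading matrices of the latent decomposition.
kernel_pls <- function(XtX, XtY, A) {
  K <- nrow(XtX); C <- ncol(XtY)
  R <- matrix(0, K, A); P <- matrix(0, K, A); Q <- matrix(0, C, A)
  S <- XtY
  for (a in seq_len(A)) {
    if (C == 1L) {
      w <- S[, 1L]
    } else {
      es <- eigen(crossprod(S), symmetric = TRUE)
      w <- S %*% es$vectors[, 1L]
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { # response variance exhausted; truncate
      R <- R[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[, seq_len(a - 1L), drop = FALSE]
      break
    }
    w <- w / nw
    j <- which.max(abs(w))               # deterministic sign
    if (w[j] < 0) w <- -w
    r <- w
    if (a > 1L) for (b in seq_len(a - 1L))
      r <- r - sum(P[, b] * w) * R[, b]
    tt <- as.numeric(crossprod(r, XtX %*% r))
    if (tt < 1e-12) {
      R <- R[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[, seq_len(a - 1L), drop = FALSE]
      break
    }
    p <- as.numeric(XtX %*% r) / tt
    q <- as.numeric(crossprod(S, r)) / tt
    S <- S - tt * tcrossprod(p, q)
    R[, a] <- r; P[, a] <- p; Q[, a] <- q
  }
  list(B = R %*% t(Q), R = R, P = P, Q = Q)
}

#' Predict from a fitted PLS-DA model
#'
#' Applies the stored preprocessing, computes the continuous response
#' `Y_hat = intercept + X_prep %*% beta` and assigns the class by arg-max
#' over the class columns (one-hot coding) or by the 0.5 cut on the single
#' 0/1 column (binary coding), which is the arg-max rule's two-class
#' special case.
#'
#' @param object an `mfi_plsda` from [plsda_fit()].
#' @param newdata spectra matrix (or single spectrum) with the training band
#'   count.
#' @param ... unused.
#' @return List with `yhat` (continuous responses) and `class` (character
#'   labels).
#' @export
predict.mfi_plsda <- function(object, newdata, ...) {
  Xn <- rbind(newdata)
  if (ncol(Xn) != length(object$x_center))
    stop("band count of new spectra does not match the fitted model")
  Xp <- rbind(prep_apply(object$prep, Xn))
  yhat <- sweep(Xp %*% object$beta, 2L, object$intercept, `+`)
  cls <- if (object$coding == "binary") {
    object$classes[1L + (yhat[, 1L] >= 0.5)]
  } else {
    object$classes[max.col(yhat, ties.method = "first")]
  }
  list(yhat = yhat, class = cls)
}

#' @rdname predict.mfi_plsda
#' @param model an `mfi_plsda`.
#' @param X_new spectra to predict.
#' @export
plsda_predict <- function(model, X_new) predict(model, X_new)

#' @export
coef.mfi_plsda <- function(object, ...) {
  rbind(`(intercept)` = object$intercept, object$beta)
}

#' @export
print.mfi_plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d band(s), %d latent variable(s), %s coding\n",
              nrow(x$beta), x$n_latent, x$coding))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  preprocessing:", x$prep$cfg$method, "\n")
  invisible(x)
}

#' Choose the number of latent variables by cross-validation
#'
#' Stratified k-fold cross-validation of the misclassification rate over a
#' range of latent-variable counts; returns the smallest count within one
#' standard error of the minimum (ties toward fewer latent variables).
#'
#' @param X,y training spectra and labels.
#' @param max_ncomp largest latent-variable count to try.
#' @param folds number of folds.
#' @param prep a [prep_config()].
#' @return List with `n_latent` (the selection) and `error` (CV
#'   misclassification rate per count).
#' @export
select_ncomp <- function(X, y, max_ncomp = 10L, folds = 10L,
                         prep = prep_config("none")) {
  X <- as.matrix(X); y <- as.character(y)
  max_ncomp <- min(max_ncomp, ncol(X), nrow(X) - 2L)
  fold_id <- stratified_folds(y, folds)
  err <- numeric(max_ncomp)
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    for (a in seq_len(max_ncomp)) {
      m <- plsda_fit(X[tr, , drop = FALSE], y[tr], n_latent = a, prep = prep)
      pr <- predict(m, X[!tr, , drop = FALSE])
      err[a] <- err[a] + sum(pr$class != y[!tr])
    }
  }
  err <- err / length(y)
  list(n_latent = which.min(err), error = err)
}

# Deterministic stratified fold assignment: round-robin within each class in
# original row order (no RNG, so results are reproducible by construction).
stratified_folds <- function(y, k) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    w <- which(y == cl)
    id[w] <- rep_len(seq_len(k), length(w))
  }
  id
}
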