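#' Classification metrics from a confusion matrix
#'
#' Rows of the confusion matrix are true classes, columns predicted classes.
#' For each class a one-vs-rest sensitivity (recall) and specificity are
#' computed.  Two accuracies are reported: `accuracy_balanced`, the mean
#' over classes of (sensitivity + specificity)/2 — the definition used for
#' the headline accuracy of the classification models in this package — and
#' `accuracy_overall`, the usual trace/total.  Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` taken from
#' the row/column marginals; if `p_e == 1` the statistic is reported as 1
#' when the observed agreement is also perfect and is an error otherwise.
#'
#' @param confusion square non-negative integer matrix with matching
#'   row/column class order.
#' @return An object of class `mfi_metrics`: `confusion`, `per_class`
#'   (data.frame with sensitivity and specificity), `accuracy_balanced`,
#'   `accuracy_overall`, `kappa`.
#' @export
confusion_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0) || any(cm != round(cm))) stop("confusion counts must be non-negative integers")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  C <- nrow(cm)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- paste0("class", seq_len(C))
  sens <- spec <- numeric(C)
  for (i in seq_len(C)) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp; tn <- total - tp - fn - fp
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (abs(1 - p_e) < 1e-12) {
    if (abs(1 - p_o) < 1e-12) 1.0 else stop("kappa undefined: chance agreement is 1 with imperfect observed agreement")
  } else (p_o - p_e) / (1 - p_e)
  structure(list(confusion = cm,
                 per_class = data.frame(class = cls, sensitivity = sens,
                                        specificity = spec),
                 accuracy_balanced = mean((sens + spec) / 2),
                 accuracy_overall = p_o,
                 kappa = kappa),
            class = "mfi_metrics")
}

#' @export
print.mfi_metrics <- function(x, ...) {
  cat("Classification metrics\n")
  print(x$confusion)
  df <- x$per_class
  df$sensitivity <- sprintf("%.3f", df$sensitivity)
  df$specificity <- sprintf("%.3f", df$specificity)
  print(df, row.names = FALSE)
  cat(sprintf("balanced accuracy %.4f | overall accuracy %.4f | kappa %.4f\n",
              x$accuracy_balanced, x$accuracy_overall, x$kappa))
  invisible(x)
}

#' Leave-one-out cross-validation of a PLS-DA model
#'
#' Each sample is predicted by a model fitted on the remaining N - 1, with
#' the preprocessing transform refitted inside every fold (no information
#' leakage); metrics are computed from the pooled predictions.  For
#' unpreprocessed spectra the per-fold model is obtained by downdating the
#' full-data cross-product matrices, which is algebraically identical to a
#' refit; other preprocessing methods refit from scratch.  Above `loo_cap`
#' samples the procedure falls back, with a warning, to stratified k-fold
#' cross-validation.
#'
#' @inheritParams plsda_fit
#' @param loo_cap largest N for which true LOO is run.
#' @param fallback_folds folds used beyond the cap.
#' @return An `mfi_metrics` (see [confusion_metrics()]) with the pooled
#'   confusion matrix; the pooled predicted labels are in attribute
#'   `"predicted"`.
#' @export
loo_cv <- function(X, y, n_latent = 3L, prep = prep_config("none"),
                   coding = c("onehot", "binary"),
                   loo_cap = 2500L, fallback_folds = 10L) {
  coding <- match.arg(coding)
  X <- as.matrix(X); y <- as.character(y)
  N <- nrow(X)
  classes <- sort(unique(y))
  if (N > loo_cap) {
    warning(sprintf("N = %d exceeds the LOO cap (%d); using stratified %d-fold CV",
                    N, loo_cap, fallback_folds))
    fold_id <- stratified_folds(y, fallback_folds)
  } else {
    fold_id <- seq_len(N)
  }
  pred <- character(N)
  if (prep$method == "none" && N <= loo_cap) {
    # fast exact LOO by downdating sums and cross-products
    Y <- class_indicator(y, classes, coding)
    G <- crossprod(X); H <- crossprod(X, Y)
    sx <- colSums(X); sy <- colSums(Y)
    for (i in seq_len(N)) {
      xi <- X[i, ]; yi <- Y[i, ]
      n1 <- N - 1L
      mx <- (sx - xi) / n1; my <- (sy - yi) / n1
      Gc <- G - tcrossprod(xi) - n1 * tcrossprod(mx)
      Hc <- H - tcrossprod(xi, yi) - n1 * tcrossprod(mx, my)
      core <- kernel_pls(Gc, Hc, n_latent)
      yhat <- my + as.numeric((xi - mx) %*% core$B)
      pred[i] <- if (coding == "binary") {
        classes[1L + (yhat[1L] >= 0.5)]
      } else classes[which.max(yhat)]
    }
  } else {
    for (f in unique(fold_id)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < length(classes))
        stop("a cross-validation fold lost a whole class; reduce folds or add data")
      m <- plsda_fit(X[tr, , drop = FALSE], y[tr], n_latent = n_latent,
                     prep = prep, coding = coding)
      pred[!tr] <- predict(m, X[!tr, , drop = FALSE])$class
    }
  }
  cm <- table(factor(y, classes), factor(pred, classes))
  out <- confusion_metrics(unclass(as.matrix(cm)))
  attr(out, "predicted") <- pred
  out
}
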