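#' Spectral preprocessing configuration
#'
#' The classification models can run on raw spectra (`"none"`), after
#' multiplicative scatter correction (`"msc"`), or on first/second
#' Savitzky-Golay derivatives (`"d1"`, `"d2"`).  The derivative window and
#' polynomial order default to 5 and 2, the smallest sensible choice on a
#' 27-band grid; derivatives are taken per band index (the grid is uniform,
#' so this differs from a per-nm derivative only by a constant factor).
#'
#' @param method `"none"`, `"msc"`, `"d1"` or `"d2"`.
#' @param sg_window odd Savitzky-Golay window length, >= 5.
#' @param sg_polyorder polynomial order, >= 2 and < `sg_window`.
#' @param msc_reference `"mean"` (column mean of the training spectra) or a
#'   numeric reference spectrum.
#' @return An object of class `prep_config`.
#' @export
prep_config <- function(method = c("none", "msc", "d1", "d2"),
                        sg_window = 5L, sg_polyorder = 2L,
                        msc_reference = "mean") {
  method <- match.arg(method)
  sg_window <- as.integer(sg_window); sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window < 5L || sg_window %% 2L == 0L)
    stop("sg_window must be an odd integer >= 5")
  if (sg_polyorder < 2L || sg_polyorder >= sg_window)
    stop("sg_polyorder must be >= 2 and < sg_window")
  deriv <- switch(method, d1 = 1L, d2 = 2L, 0L)
  if (deriv > sg_polyorder) stop("derivative order exceeds sg_polyorder")
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, msc_reference = msc_reference),
            class = "prep_config")
}

#' Multiplicative scatter correction
#'
#' MSC regresses each spectrum on a reference spectrum (by default the mean
#' spectrum of `X`, the usual artificial baseline) by ordinary least squares,
#' `x = a + b * ref`, and returns `(x - a) / b`.  This removes additive and
#' multiplicative scatter differences between spectra.  Rows whose slope `b`
#' is numerically zero (a constant spectrum against a non-constant reference)
#' cannot be corrected; they are returned unchanged and flagged in the
#' `"flagged"` attribute.
#'
#' @param X N x K spectra matrix.
#' @param reference reference spectrum of length K, or `NULL` for the column
#'   mean of `X`.
#' @return Corrected N x K matrix with attributes `"reference"` (the
#'   reference used) and `"flagged"` (integer row indices left uncorrected).
#' @export
msc <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length must equal the number of bands")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("constant reference spectrum: MSC undefined")
  b <- as.numeric(X %*% rc) / denom        # row-wise OLS slope
  a <- rowMeans(X) - b * mean(reference)
  flagged <- which(abs(b) < 1e-12)
  bs <- ifelse(abs(b) < 1e-12, 1, b)
  out <- (X - a) / bs
  out[flagged, ] <- X[flagged, , drop = FALSE]
  attr(out, "reference") <- reference
  attr(out, "flagged") <- flagged
  out
}

# Savitzky-Golay weight vectors: for output position j on a length-K grid,
# fit a polynomial of the given order over the window (truncated one-sided at
# the edges) and evaluate its deriv-th derivative at j.
savgol_weights <- function(K, window, polyorder, deriv) {
  h <- window %/% 2L
  W <- vector("list", K)
  for (j in seq_len(K)) {
    idx <- max(1L, j - h):min(K, j + h)
    if (length(idx) <= polyorder)
      stop("window truncation leaves too few points for the polynomial order")
    V <- outer(idx - j, 0:polyorder, `^`)
    # row of the pseudo-inverse picking the deriv-th coefficient, times deriv!
    Ai <- solve(crossprod(V), t(V))
    W[[j]] <- list(idx = idx, w = factorial(deriv) * Ai[deriv + 1L, ])
  }
  W
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Per-row local polynomial least-squares filtering of spectra: each band is
#' replaced by the value (or first/second derivative) of a polynomial of
#' order `polyorder` fitted over a centered window of `window` bands.  Edge
#' bands use the same fit on the truncated one-sided window, so output and
#' input have identical shape.  Derivatives are per band index.
#'
#' @param X N x K spectra matrix (a single spectrum may be given as a
#'   vector).
#' @param window odd window length.
#' @param polyorder polynomial order (< window).
#' @param deriv derivative order: 0 (smoothing), 1 or 2; must be <=
#'   `polyorder`.
#' @return Filtered matrix of the same shape as `X`.
#' @export
savgol <- function(X, window = 5L, polyorder = 2L, deriv = 1L) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  K <- ncol(X)
  W <- savgol_weights(K, window, polyorder, deriv)
  out <- matrix(0, nrow(X), K)
  for (j in seq_len(K))
    out[, j] <- X[, W[[j]]$idx, drop = FALSE] %*% W[[j]]$w
  dimnames(out) <- dimnames(X)
  if (vec) out[1, ] else out
}

#' Fit a preprocessing transform on training spectra
#'
#' MSC learns its reference from the training set; derivative filters are
#' stateless.  Fitting and applying are separated so that cross-validation
#' can refit the transform inside each fold without information leakage.
#'
#' @param X training spectra (N x K).
#' @param cfg a [prep_config()].
#' @return An object of class `prep_fit`; apply it with [prep_apply()].
#' @export
prep_fit <- function(X, cfg = prep_config("none")) {
  ref <- NULL
  if (cfg$method == "msc") {
    ref <- if (is.numeric(cfg$msc_reference)) cfg$msc_reference else colMeans(rbind(X))
  }
  structure(list(cfg = cfg, reference = ref), class = "prep_fit")
}

#' Apply a fitted preprocessing transform
#'
#' @param fit a `prep_fit` from [prep_fit()].
#' @param X spectra to transform (N x K, or a single spectrum).
#' @return Transformed spectra, same shape as `X`.
#' @export
prep_apply <- function(fit, X) {
  cfg <- fit$cfg
  switch(cfg$method,
    none = X,
    msc  = {
      out <- msc(rbind(X), reference = fit$reference)
      if (is.null(dim(X))) out[1, ] else out
    },
    d1   = savgol(X, cfg$sg_window, cfg$sg_polyorder, 1L),
    d2   = savgol(X, cfg$sg_window, cfg$sg_polyorder, 2L))
}

#' Per-class mean and standard deviation spectra
#'
#' Summarises labeled spectra per class and band (sample sd, denominator
#' N-1), the numbers behind the mean-and-spread spectra plots used to judge
#' class separability by eye.
#'
#' @param spectra a `labeled_spectra` (see [extract_roi_spectra()]).
#' @return A list per class with elements `mean` and `sd` (K-vectors), plus
#'   attribute `"axis"`.
#' @export
class_mean_sd <- function(spectra) {
  out <- list()
  for (cls in unique(spectra$y)) {
    rows <- spectra$X[spectra$y == cls, , drop = FALSE]
    if (nrow(rows) < 2L)
      stop(sprintf("class '%s' has fewer than 2 spectra", cls))
    out[[cls]] <- list(mean = colMeans(rows), sd = apply(rows, 2, sd))
  }
  attr(out, "axis") <- spectra$axis
  out
}
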