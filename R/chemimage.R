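#' Chemical image container
#'
#' A chemical image is a single-channel float image derived from a spectral
#' model — a band ratio, a principal-component score image, a PLS-DA
#' regression projection or an enhanced color channel — together with the
#' provenance of how it was produced.
#'
#' @param data numeric matrix.
#' @param kind one of `"ratio"`, `"pc_score"`, `"beta_projection"`,
#'   `"color_channel"`.
#' @param params list of provenance parameters.
#' @return An object of class `chemical_image`.
#' @export
chemical_image <- function(data, kind, params = list()) {
  stopifnot(is.matrix(data))
  structure(list(data = data,
                 provenance = list(kind = kind, params = params),
                 scale8 = NULL),
            class = "chemical_image")
}

#' @export
print.chemical_image <- function(x, ...) {
  cat(sprintf("Chemical image (%s): %d x %d, range [%.4g, %.4g]\n",
              x$provenance$kind, nrow(x$data), ncol(x$data),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
plot.chemical_image <- function(x, ...) {
  image(t(x$data[nrow(x$data):1, ]), col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, ...)
  invisible(x)
}

#' Band-ratio image
#'
#' Pixelwise ratio of fluorescence at two band centers (nearest-band
#' lookup), e.g. F630/F600, the key contrast between porphyrin-rich fecal
#' spots and skin.  Pixels whose denominator falls below `eps` are flagged
#' invalid and set to 0.
#'
#' @param cube a [spectral_cube()].
#' @param num_nm,den_nm numerator and denominator wavelengths in nm.
#' @param eps guard for near-zero denominators.
#' @return A `chemical_image`; the logical matrix of invalid pixels is in
#'   attribute `"invalid"` of `$data`.
#' @export
band_ratio <- function(cube, num_nm = 630, den_nm = 600, eps = 1e-3) {
  bi <- nearest_band(cube$axis, num_nm)
  bj <- nearest_band(cube$axis, den_nm)
  num <- cube$data[, , bi]
  den <- cube$data[, , bj]
  invalid <- den < eps
  out <- num / pmax(den, eps)
  out[invalid] <- 0
  attr(out, "invalid") <- invalid
  chemical_image(out, "ratio",
                 list(num_nm = cube$axis[bi], den_nm = cube$axis[bj], eps = eps))
}

#' Per-class kernel density of a chemical image
#'
#' Gaussian kernel density estimates of the image values inside each truth
#' class region (upper spots, bottom spots, contamination-free skin), the
#' numeric content of a band-ratio density plot.  Bandwidths follow
#' Silverman's rule; a single-valued class degenerates to a spike at that
#' value (an epsilon bandwidth is substituted).
#'
#' @param image a `chemical_image`.
#' @param truth ground truth from [render_scene()].
#' @return Named list of `stats::density` objects (`upper`, `bottom`,
#'   `skin`).
#' @export
ratio_density_by_class <- function(image, truth) {
  vals <- list(
    upper  = image$data[class_union_mask(truth, "upper")],
    bottom = image$data[class_union_mask(truth, "bottom")],
    skin   = image$data[truth$skin_only_mask])
  lapply(vals, function(v) {
    if (length(v) == 0L) stop("empty class mask")
    bw <- if (length(unique(v)) < 2L) 1e-6 * (1 + abs(v[1])) else "nrd0"
    density(v, bw = bw)
  })
}

class_union_mask <- function(truth, class) {
  m <- matrix(FALSE, nrow(truth$skin_mask), ncol(truth$skin_mask))
  for (s in truth$spots) if (s$class == class) m <- m | s$mask
  if (!any(m)) stop("empty class mask: ", class)
  m
}

#' Principal-component score image
#'
#' Projects every pixel spectrum of a cube onto one loading of a fitted PCA
#' model (after centering with the model's center), producing a score image
#' in which chemically distinct regions stand out.  In this pipeline the
#' second component typically isolates the porphyrin emission contrast of
#' fecal spots from overall brightness variation, which loads on the first.
#'
#' @param cube a [spectral_cube()].
#' @param pca_model an `mfi_pca` fitted on spectra with the same axis.
#' @param component component index.
#' @return A `chemical_image` with kind `"pc_score"`.
#' @export
pc_score_image <- function(cube, pca_model, component = 2L) {
  if (component < 1L || component > ncol(pca_model$loadings))
    stop("component out of range for the fitted model")
  d <- dim(cube$data)
  sc <- pca_project(pca_model, cube_to_matrix(cube))[, component]
  chemical_image(matrix(sc, d[1], d[2]), "pc_score",
                 list(component = as.integer(component)))
}

#' PLS-DA coefficient projection image
#'
#' Applies a fitted PLS-DA model's beta coefficients to every pixel spectrum
#' of a cube and returns the continuous prediction for one class as an
#' image.  Values near 1 indicate pixels resembling that class's training
#' spectra; the image is binarizable at 0.5 (binary coding) or via the
#' arg-max map across classes.
#'
#' @param cube a [spectral_cube()].
#' @param plsda_model an `mfi_plsda`.
#' @param class class whose response column is rendered.
#' @return A `chemical_image` with kind `"beta_projection"`; the arg-max
#'   class map is attached as attribute `"class_map"` of `$data` (one-hot
#'   models only).
#' @export
beta_projection_image <- function(cube, plsda_model, class) {
  cols <- colnames(class_indicator(plsda_model$classes, plsda_model$classes,
                                   plsda_model$coding))
  if (!class %in% cols)
    stop("class '", class, "' not among the model's response columns")
  d <- dim(cube$data)
  pr <- predict(plsda_model, cube_to_matrix(cube))
  img <- matrix(pr$yhat[, class], d[1], d[2])
  attr(img, "class_map") <- matrix(pr$class, d[1], d[2])
  chemical_image(img, "beta_projection", list(class = class))
}

#' Scale a float image to 8 bits
#'
#' Linear min-max scaling to 0..255 after optional percentile clipping; the
#' (min, max) actually used are recorded in the `"range"` attribute so the
#' mapping is invertible to within 1/255 of the range.  Needed because the
#' histogram auto-thresholding methods operate on 0-255 gray levels.
#'
#' @param image a `chemical_image` or numeric matrix.
#' @param clip_low_pct,clip_high_pct percentiles (0-100) clipped at each end
#'   before scaling.
#' @return Integer matrix with values 0..255 and attribute `"range"`; a
#'   constant image maps to all zeros with a warning.
#' @export
to_8bit <- function(image, clip_low_pct = 0, clip_high_pct = 0) {
  m <- if (inherits(image, "chemical_image")) image$data else image
  if (any(!is.finite(m))) stop("image must be finite")
  lo <- as.numeric(quantile(m, clip_low_pct / 100))
  hi <- as.numeric(quantile(m, 1 - clip_high_pct / 100))
  if (hi <= lo) {
    warning("constant image: mapped to all zeros")
    out <- matrix(0L, nrow(m), ncol(m))
    attr(out, "range") <- c(lo, lo)
    return(out)
  }
  z <- (pmin(pmax(m, lo), hi) - lo) / (hi - lo)
  out <- matrix(as.integer(round(255 * z)), nrow(m), ncol(m))
  attr(out, "range") <- c(lo, hi)
  out
}
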