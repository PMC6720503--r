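#' Spectral cube container
#'
#' A spectral cube is a lines x pixels x bands array of non-negative
#' fluorescence intensities with a wavelength axis and free-form acquisition
#' metadata.  This is the raw datum the whole package operates on: each pixel
#' along each scan line carries a full 27-band emission spectrum.
#'
#' @param data numeric 3-D array (lines x pixels x bands), finite and
#'   non-negative.
#' @param axis numeric wavelength axis; its length must equal `dim(data)[3]`.
#' @param meta list of acquisition metadata (e.g. `speed_bps`, `source`).
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, axis = default_wavelength_axis(), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("cube data must be a 3-D array (lines x pixels x bands)")
  if (dim(data)[3] != length(axis))
    stop(sprintf("band dimension (%d) does not match wavelength axis length (%d)",
                 dim(data)[3], length(axis)))
  if (anyNA(data) || any(!is.finite(data)))
    stop("cube data must be finite")
  if (any(data < 0))
    stop("cube data must be non-negative (fluorescence intensities)")
  structure(list(data = data, axis = axis, meta = meta),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Spectral cube: %d lines x %d pixels x %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis)))
  if (length(x$meta)) {
    keys <- vapply(names(x$meta), function(k)
      sprintf("%s=%s", k, format(x$meta[[k]])[1]), "")
    cat("  meta:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a cube to a pixel-by-band spectra matrix
#'
#' @param cube a [spectral_cube()].
#' @return Matrix of dimension (lines*pixels) x bands; rows are in column-major
#'   (line-fastest) order so that `matrix(v, lines, pixels)` restores images.
#' @export
cube_to_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, d[1] * d[2], d[3])
}
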