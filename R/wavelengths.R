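#' Default wavelength axis of the line-scan fluorescence imager
#'
#' The instrument modelled here records 27 fluorescence bands between 410 and
#' 690 nm at roughly 11 nm spectral resolution (a 400 nm long-pass filter
#' blocks the UV-A excitation).  The default axis places the 27 band centers
#' evenly on that range, i.e. a spacing of 280/26 (about 10.77) nm.
#'
#' @return Numeric vector of 27 band-center wavelengths in nm.
#' @examples
#' wl <- default_wavelength_axis()
#' length(wl)    # 27
#' range(wl)     # 410 690
#' @export
default_wavelength_axis <- function() {
  seq(410, 690, length.out = 27L)
}

#' Validate a wavelength axis
#'
#' Checks the contract every axis used by the package must satisfy: strictly
#' increasing centers, within 400-700 nm, adjacent spacing between 10 and
#' 12 nm (the instrument's nominal resolution).
#'
#' @param centers numeric vector of band centers in nm.
#' @return `centers`, invisibly, after validation.
#' @export
validate_wavelength_axis <- function(centers) {
  if (!is.numeric(centers) || length(centers) < 2L)
    stop("wavelength axis must be a numeric vector of band centers")
  d <- diff(centers)
  if (any(d <= 0)) stop("wavelength axis must be strictly increasing")
  if (centers[1L] < 400) stop("first band center below the 400 nm long-pass cutoff")
  if (centers[length(centers)] > 700) stop("last band center above 700 nm")
  if (any(d < 10 - 1e-9) || any(d > 12 + 1e-9))
    stop("adjacent band spacing outside the nominal 10-12 nm resolution")
  invisible(centers)
}

#' Index of the band nearest a target wavelength
#'
#' @param axis numeric wavelength axis (nm).
#' @param nm target wavelength in nm; must lie within the axis range.
#' @return Integer band index.  Ties between two equally close neighbours go
#'   to the lower band.
#' @export
nearest_band <- function(axis, nm) {
  if (nm < min(axis) || nm > max(axis))
    stop(sprintf("wavelength %.1f nm outside axis range [%.1f, %.1f]",
                 nm, min(axis), max(axis)))
  which.min(abs(axis - nm))
}
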