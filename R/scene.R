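#' Configuration of a synthetic line-scan fluorescence scene
#'
#' Builds the parameter set for [render_scene()].  The defaults emulate the
#' study conditions the package is designed around: carcasses carrying four
#' 50 uL fecal spots each (two strongly fluorescing "upper" spots from
#' ceca/colon material, two weak "bottom" spots from small-intestine/duodenum
#' material) on weakly fluorescing skin, scanned line-by-line at 1, 3 or 5
#' birds per second.  Higher conveyor speed is modelled as along-track line
#' decimation at fixed per-line exposure: a bird covered by
#' `lines_per_bird_at_1bps` scan lines at 1 bird/s is covered by
#' `lines_per_bird_at_1bps %/% speed_bps` lines at higher speeds.
#'
#' Fluorescence intensities are in arbitrary detector units.  The fecal
#' emission is a Gaussian protoporphyrin-IX-like peak: ceca/colon material
#' emits at 635 nm while small-intestine/duodenum material peaks slightly
#' lower, near 630 nm, so `peak_center_nm` takes one center per class
#' (default `c(upper = 635, bottom = 630)`; a scalar applies to both).
#' `spot_amplitudes` fixes the peak height per class, with
#' `upper > bottom > 0`.  The carcass carries a per-pixel multiplicative
#' brightness texture (log-normal, mean 1, log-sd `texture_sd`) on the skin
#' baseline — the deposit emission originates in the fecal material itself
#' and is not modulated by skin texture; detector noise is additive
#' Gaussian with standard deviation `noise_sd`, clipped at zero.
#'
#' @param lines_per_bird_at_1bps scan lines covering one bird at 1 bird/s.
#' @param pixels_per_line pixels across the scan line.
#' @param speed_bps conveyor speed in birds per second; one of 1, 3, 5.
#' @param n_birds number of birds in the scene (stacked along track).
#' @param spot_radius_px fecal spot radius in pixels (1 bird/s geometry).
#' @param spot_amplitudes named list/vector with peak fluorescence amplitudes
#'   `upper` and `bottom` (arbitrary units).
#' @param peak_center_nm center(s) of the fecal emission peak in nm; scalar
#'   or named vector with `upper` and `bottom` entries.
#' @param peak_fwhm_nm full width at half maximum of the emission peak in
#'   nm; scalar or named vector with `upper` and `bottom` entries.  The
#'   bottom-class deposit (a mixed bile/porphyrin material) emits a broader,
#'   less pure band than the ceca/colon material, hence the wider default.
#' @param skin_level overall skin fluorescence level (arbitrary units).
#' @param texture_sd log-sd of the multiplicative skin brightness texture.
#' @param noise_sd additive detector noise standard deviation.
#' @param seed integer seed; identical configurations give bit-identical
#'   scenes.
#' @return An object of class `scene_config` (a validated list).
#' @export
scene_config <- function(lines_per_bird_at_1bps = 120L,
                         pixels_per_line = 120L,
                         speed_bps = 1L,
                         n_birds = 1L,
                         spot_radius_px = 7L,
                         spot_amplitudes = c(upper = 1.0, bottom = 0.35),
                         peak_center_nm = c(upper = 635, bottom = 630),
                         peak_fwhm_nm = c(upper = 25, bottom = 32),
                         skin_level = 0.8,
                         texture_sd = 0.35,
                         noise_sd = 0.05,
                         seed = 42L) {
  cfg <- list(lines_per_bird_at_1bps = as.integer(lines_per_bird_at_1bps),
              pixels_per_line = as.integer(pixels_per_line),
              speed_bps = as.integer(speed_bps),
              n_birds = as.integer(n_birds),
              spot_radius_px = as.integer(spot_radius_px),
              spot_amplitudes = c(upper = unname(spot_amplitudes[["upper"]]),
                                  bottom = unname(spot_amplitudes[["bottom"]])),
              peak_center_nm = if (length(peak_center_nm) == 1L) {
                c(upper = unname(peak_center_nm), bottom = unname(peak_center_nm))
              } else {
                c(upper = unname(peak_center_nm[["upper"]]),
                  bottom = unname(peak_center_nm[["bottom"]]))
              },
              peak_fwhm_nm = if (length(peak_fwhm_nm) == 1L) {
                c(upper = unname(peak_fwhm_nm), bottom = unname(peak_fwhm_nm))
              } else {
                c(upper = unname(peak_fwhm_nm[["upper"]]),
                  bottom = unname(peak_fwhm_nm[["bottom"]]))
              },
              skin_level = skin_level,
              texture_sd = texture_sd,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (!cfg$speed_bps %in% c(1L, 3L, 5L))
    stop("speed_bps must be 1, 3 or 5 (birds per second)")
  if (!(cfg$spot_amplitudes[["upper"]] > cfg$spot_amplitudes[["bottom"]] &&
        cfg$spot_amplitudes[["bottom"]] > 0))
    stop("spot amplitudes must satisfy upper > bottom > 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$texture_sd < 0) stop("texture_sd must be >= 0")
  if (cfg$n_birds < 1L) stop("n_birds must be >= 1")
  class(cfg) <- "scene_config"
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Synthetic line-scan scene configuration\n")
  cat(sprintf("  %d bird(s) at %d bird/s: %d lines/bird x %d pixels\n",
              x$n_birds, x$speed_bps,
              x$lines_per_bird_at_1bps %/% x$speed_bps, x$pixels_per_line))
  cat(sprintf("  spots: r=%d px, amplitudes upper=%.2f bottom=%.2f, peaks %.0f/%.0f nm (FWHM %.0f)\n",
              x$spot_radius_px, x$spot_amplitudes[["upper"]],
              x$spot_amplitudes[["bottom"]], x$peak_center_nm[["upper"]],
              x$peak_center_nm[["bottom"]], x$peak_fwhm_nm[["upper"]]))
  cat(sprintf("  skin level %.2f, texture sd %.2f, noise sd %.3f, seed %d\n",
              x$skin_level, x$texture_sd, x$noise_sd, x$seed))
  invisible(x)
}

#' Baseline skin fluorescence spectrum
#'
#' Chicken skin under UV-A excitation fluoresces weakly and smoothly: there is
#' a signal valley around 490 nm and a slope ascension near 515 nm, but no
#' emission peak anywhere in 500-680 nm.  The model is a broad baseline
#' multiplied by a Gaussian dip at 490 nm and a soft logistic rise centered at
#' 515 nm, scaled by `skin_level`; by construction the max/min ratio over
#' 500-680 nm stays below 1.3.
#'
#' @param axis wavelength axis in nm (see [default_wavelength_axis()]).
#' @param cfg a [scene_config()] (only `skin_level` is used).
#' @return Numeric vector of per-band skin fluorescence, same length as
#'   `axis`.
#' @export
skin_spectrum <- function(axis = default_wavelength_axis(), cfg = scene_config()) {
  if (cfg$skin_level < 0) stop("skin_level must be non-negative")
  broad <- exp(-((axis - 520) / 600)^2)
  dip   <- 1 - 0.2 * exp(-((axis - 490)^2) / (2 * 9^2))
  rise  <- 0.85 + 0.15 / (1 + exp(-(axis - 515) / 12))
  cfg$skin_level * broad * dip * rise
}

#' Fecal-spot fluorescence spectrum
#'
#' A fecal spot adds a Gaussian porphyrin emission peak (centered near
#' 633 nm) on top of the skin spectrum.  Material from the ceca and colon
#' ("upper" class) fluoresces strongly; material from the small intestine and
#' duodenum ("bottom" class) gives a comparatively small peak near 630 nm.
#'
#' @param class `"upper"` or `"bottom"`.
#' @inheritParams skin_spectrum
#' @return Numeric per-band spectrum, same length as `axis`.
#' @export
fecal_spectrum <- function(class = c("upper", "bottom"),
                           axis = default_wavelength_axis(),
                           cfg = scene_config()) {
  class <- match.arg(class)
  amp <- cfg$spot_amplitudes[[class]]
  skin_spectrum(axis, cfg) + amp * peak_shape(axis, cfg, class)
}

# unit-height Gaussian emission peak on the band grid
peak_shape <- function(axis, cfg, class = "upper") {
  sigma <- cfg$peak_fwhm_nm[[class]] / (2 * sqrt(2 * log(2)))
  exp(-((axis - cfg$peak_center_nm[[class]])^2) / (2 * sigma^2))
}

# Deterministic spot layout for one bird, in 1 bird/s along-track units.
# Two spots in the upper third of the carcass ellipse, two in the lower
# third, jittered by the supplied RNG-drawn offsets.
bird_spot_centers <- function(L1, P, r, jitter) {
  cy <- L1 / 2; cx <- P / 2
  ay <- 0.45 * L1; ax <- 0.40 * P
  base <- rbind(
    c(cy - 0.55 * ay, cx - 0.40 * ax, 1),  # upper pair (ceca / colon)
    c(cy - 0.55 * ay, cx + 0.40 * ax, 1),
    c(cy + 0.55 * ay, cx - 0.40 * ax, 2),  # bottom pair (SI / duodenum)
    c(cy + 0.55 * ay, cx + 0.40 * ax, 2))
  base[, 1:2] <- base[, 1:2] + jitter
  # clamp into the ellipse with a safety margin of r + 2 px
  for (i in 1:4) {
    y <- base[i, 1]; x <- base[i, 2]
    f <- sqrt(((y - cy) / (ay - r - 2))^2 + ((x - cx) / (ax - r - 2))^2)
    if (f > 1) {
      base[i, 1] <- cy + (y - cy) / f
      base[i, 2] <- cx + (x - cx) / f
    }
  }
  base
}

#' Render a synthetic multispectral fluorescence scene
#'
#' Generates a spectral cube and pixel-accurate ground truth for `n_birds`
#' carcasses on a dark conveyor background.  Each carcass is a filled ellipse
#' of skin spectrum carrying four circular fecal spots (two upper-class, two
#' bottom-class).  Conveyor speed decimates scan lines along track
#' (`lines_per_bird_at_1bps %/% speed_bps` lines per bird); spots therefore
#' appear vertically compressed at higher speed, as in a push-broom scan of a
#' faster line.  The noiseless signal (including the seeded brightness
#' texture) is laid down first; additive Gaussian noise (`noise_sd`) is then
#' applied and values are clipped at zero.  Identical configurations produce
#' bit-identical output.
#'
#' @param cfg a [scene_config()].
#' @return A list of class `mfi_scene` with elements:
#'   \describe{
#'     \item{cube}{a [spectral_cube()] of dimension lines x pixels x bands.}
#'     \item{truth}{ground truth: `spots` (list with `mask` logical matrix,
#'       `class`, `centroid` (line, pixel; 0-based), `area_px`,
#'       `expected_spectrum` = mean noiseless spectrum over the spot mask),
#'       `skin_mask` (carcass ellipse), `skin_only_mask` (skin minus spots),
#'       and `expected_skin_spectrum`.}
#'     \item{cfg}{the configuration used.}
#'   }
#' @export
render_scene <- function(cfg = scene_config()) {
  axis <- default_wavelength_axis()
  K <- length(axis)
  L1 <- cfg$lines_per_bird_at_1bps
  nl_bird <- L1 %/% cfg$speed_bps
  if (nl_bird < 4L) stop("too few scan lines per bird at this speed")
  P <- cfg$pixels_per_line
  nl <- nl_bird * cfg$n_birds
  r <- cfg$spot_radius_px

  skin <- skin_spectrum(axis, cfg)
  peaks <- list(upper = peak_shape(axis, cfg, "upper"),
                bottom = peak_shape(axis, cfg, "bottom"))
  amps <- c(upper = cfg$spot_amplitudes[["upper"]],
            bottom = cfg$spot_amplitudes[["bottom"]])

  old <- .Random.seed_exists()
  set.seed(cfg$seed)

  skin_mask <- matrix(FALSE, nl, P)
  amp_img <- list(upper = matrix(0, nl, P), bottom = matrix(0, nl, P))
  spots <- list()
  px <- seq_len(P) - 0.5                  # pixel centers, 0-based convention
  for (b in seq_len(cfg$n_birds)) {
    jitter <- matrix(runif(8, -3, 3), 4, 2)
    centers <- bird_spot_centers(L1, P, r, jitter)
    line0 <- (b - 1L) * nl_bird
    # along-track coordinate of each scene line, in 1 bird/s units
    tl <- (seq_len(nl_bird) - 0.5) * cfg$speed_bps
    cy <- L1 / 2; cx <- P / 2
    ay <- 0.45 * L1; ax <- 0.40 * P
    ell <- outer(((tl - cy) / ay)^2, ((px - cx) / ax)^2, `+`) <= 1
    skin_mask[line0 + seq_len(nl_bird), ] <- ell
    for (s in 1:4) {
      sy <- centers[s, 1]; sx <- centers[s, 2]
      cls <- if (centers[s, 3] == 1) "upper" else "bottom"
      m <- outer((tl - sy)^2, (px - sx)^2, `+`) <= r^2
      if (!any(m)) stop("spot not placeable inside the carcass at this radius/speed")
      if (!all(ell[m])) stop("spot mask extends outside the carcass ellipse")
      full <- matrix(FALSE, nl, P)
      full[line0 + seq_len(nl_bird), ] <- m
      amp_img[[cls]][full] <- amps[[cls]]
      idx <- which(full, arr.ind = TRUE)
      spots[[length(spots) + 1L]] <- list(
        mask = full, class = cls, area_px = sum(full),
        centroid = c(line = mean(idx[, 1]) - 1, pixel = mean(idx[, 2]) - 1))
    }
  }

  gain <- matrix(1, nl, P)
  if (cfg$texture_sd > 0) {
    g <- exp(rnorm(nl * P, -cfg$texture_sd^2 / 2, cfg$texture_sd))
    gain <- matrix(g, nl, P)
  }
  gain[!skin_mask] <- 1

  # The brightness texture modulates the skin baseline only: the deposit's
  # porphyrin emission originates in the fecal material itself and adds on
  # top unmodulated.
  signal <- array(0, dim = c(nl, P, K))
  base <- gain * skin_mask
  for (k in seq_len(K))
    signal[, , k] <- base * skin[k] +
      amp_img$upper * peaks$upper[k] + amp_img$bottom * peaks$bottom[k]

  # expected mean spectra over truth masks, before noise (closed form:
  # mean gain over the mask scales the skin curve, mean amplitude the peak)
  skin_only <- skin_mask
  for (s in spots) skin_only <- skin_only & !s$mask
  for (i in seq_along(spots)) {
    m <- spots[[i]]$mask
    cls <- spots[[i]]$class
    spots[[i]]$expected_spectrum <-
      mean(base[m]) * skin + mean(amp_img[[cls]][m]) * peaks[[cls]]
  }
  expected_skin <- mean(base[skin_only]) * skin

  data <- signal
  if (cfg$noise_sd > 0) {
    data <- data + array(rnorm(length(data), 0, cfg$noise_sd), dim = dim(data))
    data[data < 0] <- 0
  }
  .Random.seed_restore(old)

  cube <- spectral_cube(data, axis,
                        meta = list(speed_bps = cfg$speed_bps,
                                    source = sprintf("synthetic seed %d", cfg$seed)))
  truth <- list(spots = spots, skin_mask = skin_mask,
                skin_only_mask = skin_only,
                expected_skin_spectrum = expected_skin)
  structure(list(cube = cube, truth = truth, cfg = cfg), class = "mfi_scene")
}

#' @export
print.mfi_scene <- function(x, ...) {
  d <- dim(x$cube$data)
  cat(sprintf("Synthetic MFI scene: %d x %d x %d cube, %d truth spot(s)\n",
              d[1], d[2], d[3], length(x$truth$spots)))
  print(x$cfg)
  invisible(x)
}

#' Render the matching 8-bit color image of a scene
#'
#' Emulates the color camera view of the same carcass under diffuse halogen
#' illumination: bright background (well-lit stainless line), mid-tone skin
#' with smooth low-frequency shading (a color camera sees gentle illumination
#' gradients rather than the per-pixel fluorescence texture), and fecal
#' spots that are darker and browner than skin, most strongly in the blue
#' channel (so downstream blue-channel processing is exercised).  The same
#' seed discipline as [render_scene()] applies; identical inputs give
#' bit-identical images.
#'
#' @param scene an `mfi_scene` from [render_scene()] (its truth and cfg are
#'   used).
#' @param noise_sd additive Gaussian noise on 0-255 gray levels.
#' @return Integer array lines x pixels x 3 with values in 0..255.
#' @export
render_rgb <- function(scene, noise_sd = 2) {
  truth <- scene$truth; cfg <- scene$cfg
  nl <- nrow(truth$skin_mask); P <- ncol(truth$skin_mask)
  old <- .Random.seed_exists()
  set.seed(cfg$seed + 7L)
  shade <- exp(smooth_field(nl, P, n_knots = 8L, sd = 0.06))

  col_bg   <- c(225, 228, 232)
  col_skin <- c(205, 170, 140)
  col_spot <- list(upper = c(110, 70, 30), bottom = c(140, 105, 55))

  img <- array(0, dim = c(nl, P, 3))
  for (ch in 1:3) {
    plane <- matrix(col_bg[ch], nl, P)
    plane[truth$skin_mask] <- (col_skin[ch] * shade)[truth$skin_mask]
    for (s in truth$spots)
      plane[s$mask] <- (col_spot[[s$class]][ch] * shade)[s$mask]
    img[, , ch] <- plane
  }
  if (noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
  .Random.seed_restore(old)
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}

#' Simulate a full scene (spectral cube, ground truth, color image)
#'
#' Convenience wrapper: [render_scene()] plus [render_rgb()].
#'
#' @inheritParams render_scene
#' @return An `mfi_scene` with an additional `rgb` element.
#' @export
simulate_scene <- function(cfg = scene_config()) {
  sc <- render_scene(cfg)
  sc$rgb <- render_rgb(sc)
  sc
}

# Smooth random shading field: iid Gaussian knots on a coarse grid,
# bilinearly upsampled to the image size.  Draws n_knots^2 values from the
# current RNG stream.
smooth_field <- function(nl, P, n_knots = 8L, sd = 0.06) {
  g <- matrix(rnorm(n_knots * n_knots, 0, sd), n_knots, n_knots)
  kx <- seq(0, 1, length.out = n_knots)
  rows <- t(apply(g, 1, function(r)
    approx(kx, r, xout = seq(0, 1, length.out = P))$y))
  apply(rows, 2, function(cc)
    approx(kx, cc, xout = seq(0, 1, length.out = nl))$y)
}

# Save/restore global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
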