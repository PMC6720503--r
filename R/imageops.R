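#' 256-bin histogram of an 8-bit image
#'
#' @param image8 integer matrix with values 0..255.
#' @return Integer vector of length 256 (`counts[g + 1]` is the count of
#'   gray level `g`).
#' @export
hist256 <- function(image8) {
  v <- as.integer(image8)
  if (any(v < 0L | v > 255L)) stop("image values must be in 0..255")
  tabulate(v + 1L, nbins = 256L)
}

check_image8 <- function(image8) {
  if (!is.matrix(image8)) stop("expected an image matrix")
  v <- image8
  if (any(v < 0 | v > 255) || any(v != round(v)))
    stop("expected an 8-bit image (integer values 0..255)")
  matrix(as.integer(v), nrow(image8), ncol(image8))
}

#' Histogram equalization with tail saturation
#'
#' Contrast enhancement in the style of the classical equalize step: a
#' fraction `saturated_pct` of pixels (half per tail) is clipped, then gray
#' levels are remapped by the cumulative histogram so the output fills
#' 0..255.  The mapping is monotone non-decreasing, so pixel rank order is
#' preserved.
#'
#' @param image8 8-bit image matrix.
#' @param saturated_pct percentage of pixels saturated in total (default
#'   0.3, i.e. 0.15% per tail).
#' @return Equalized 8-bit integer matrix.
#' @export
hist_equalize <- function(image8, saturated_pct = 0.3) {
  img <- check_image8(image8)
  n <- length(img)
  h <- tabulate(as.integer(img) + 1L, 256L)
  clip_n <- floor(n * saturated_pct / 200)  # per tail
  cum <- cumsum(h)
  lo <- which(cum > clip_n)[1L] - 1L
  hi <- 255L - (which(cumsum(rev(h)) > clip_n)[1L] - 1L)
  if (hi <= lo) hi <- lo + 1L
  clipped <- pmin(pmax(as.integer(img), lo), hi)
  h2 <- tabulate(clipped + 1L, 256L)
  cdf <- cumsum(h2)
  cdf_min <- cdf[lo + 1L]
  lut <- if (n == cdf_min) {
    rep(0L, 256L)
  } else {
    as.integer(round(255 * pmax(cdf - cdf_min, 0) / (n - cdf_min)))
  }
  out <- matrix(lut[clipped + 1L], nrow(img), ncol(img))
  out
}

#' Sharpening filter
#'
#' 3x3 convolution with the classical sharpening kernel
#' `[[-1,-1,-1],[-1,12,-1],[-1,-1,-1]] / 4` (edge pixels use replicated
#' borders), clipped back to 0..255.
#'
#' @param image8 8-bit image matrix.
#' @return Sharpened 8-bit integer matrix.
#' @export
sharpen <- function(image8) {
  img <- check_image8(image8)
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  acc <- 12 * img
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    acc <- acc - pad[(2L + dy):(nr + 1L + dy), (2L + dx):(nc + 1L + dx)]
  }
  out <- round(acc / 4)
  out[out < 0] <- 0L
  out[out > 255] <- 255L
  matrix(as.integer(out), nr, nc)
}

#' Median filter over a disc neighbourhood
#'
#' Replaces each pixel by the median over the disc of pixels within
#' Euclidean distance `radius` (13 pixels at radius 2.0, the neighbourhood
#' the classical radius-2.0 rank filter uses); pixels near the border use
#' the reduced neighbourhood that fits inside the image.
#'
#' @param image8 8-bit image matrix.
#' @param radius disc radius in pixels, > 0.
#' @return Filtered 8-bit integer matrix.
#' @export
median_filter <- function(image8, radius = 2.0) {
  if (radius <= 0) stop("radius must be > 0")
  img <- check_image8(image8)
  r <- floor(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, ]
  out <- median_disc_cpp(img, as.integer(off$dy), as.integer(off$dx))
  matrix(as.integer(out), nrow(img), ncol(img))
}

#' Shanbhag auto-threshold
#'
#' Automatic threshold selection by Shanbhag's fuzzy-membership information
#' measure: for each candidate threshold the average information of the two
#' gray-level classes is computed with memberships attenuated by distance
#' from the threshold, and the threshold minimizing the absolute difference
#' of the two class informations is returned (as in the widely used
#' Auto_Threshold port).  Ties break toward the lower threshold.
#'
#' @param hist integer vector of 256 bin counts ([hist256()]).
#' @return Integer threshold in 0..255.
#' @export
threshold_shanbhag <- function(hist) {
  h <- as.numeric(hist)
  if (length(h) != 256L) stop("expected a 256-bin histogram")
  if (sum(h > 0) < 2L) stop("histogram needs at least two non-empty bins")
  p <- h / sum(h)
  P1 <- cumsum(p)
  P2 <- 1 - P1
  first <- which(P1 > 0)[1L] - 1L              # gray levels, 0-based
  last  <- max(which(p > 0)) - 1L
  best_t <- -1L; best <- Inf
  for (t in first:last) {
    if (P1[t + 1L] <= 0 || P2[t + 1L] <= 0) next
    term <- 0.5 / P1[t + 1L]
    ent_back <- 0
    if (t >= 1L) {
      ih <- 1:t
      ent_back <- -sum(p[ih + 1L] * log(1 - term * P1[ih]))
    }
    ent_back <- ent_back * term
    term <- 0.5 / P2[t + 1L]
    ent_obj <- 0
    if (t + 1L <= 255L) {
      ih <- (t + 1L):255L
      ent_obj <- -sum(p[ih + 1L] * log(1 - term * P2[ih + 1L]))
    }
    ent_obj <- ent_obj * term
    tot <- abs(ent_back - ent_obj)
    if (tot < best) { best <- tot; best_t <- t }
  }
  as.integer(best_t)
}

#' Huang fuzzy auto-threshold
#'
#' Automatic threshold selection minimizing Huang's measure of fuzziness:
#' for each candidate threshold, pixel memberships
#' `mu(g) = 1 / (1 + |g - m_class| / C)` (with `m_class` the rounded mean
#' gray level of the pixel's side and `C` the histogram's dynamic range) are
#' scored by the Shannon entropy function, and the threshold with minimal
#' total fuzziness is returned.  Ties break toward the lower threshold.
#' Shifting all gray levels by a constant shifts the threshold by the same
#' constant.
#'
#' @param hist integer vector of 256 bin counts ([hist256()]).
#' @return Integer threshold in 0..255.
#' @export
threshold_huang <- function(hist) {
  h <- as.numeric(hist)
  if (length(h) != 256L) stop("expected a 256-bin histogram")
  nz <- which(h > 0)
  if (length(nz) < 2L) stop("histogram needs at least two non-empty bins")
  first <- nz[1L] - 1L; last <- nz[length(nz)] - 1L
  g <- 0:255
  S <- cumsum(h)
  W <- cumsum(h * g)
  C <- last - first
  # entropy of the membership value for each possible |g - mu| distance
  dist <- 0:C
  mu <- 1 / (1 + dist / C)
  Smu <- -mu * log(mu) - (1 - mu) * log(1 - mu)
  Smu[1L] <- 0                                 # mu = 1 contributes nothing
  best_t <- first; best <- Inf
  for (t in first:(last - 1L)) {
    mu0 <- round(W[t + 1L] / S[t + 1L])
    i0 <- first:t
    e <- sum(Smu[pmin(abs(i0 - mu0), C) + 1L] * h[i0 + 1L])
    mu1 <- round((W[last + 1L] - W[t + 1L]) / (S[last + 1L] - S[t + 1L]))
    i1 <- (t + 1L):last
    e <- e + sum(Smu[pmin(abs(i1 - mu1), C) + 1L] * h[i1 + 1L])
    if (e < best) { best <- e; best_t <- t }
  }
  as.integer(best_t)
}

#' Apply a threshold to an 8-bit image
#'
#' @param image8 8-bit image matrix.
#' @param t threshold in 0..255.
#' @param polarity `"above"` keeps pixels with value > t (bright targets);
#'   `"below"` keeps pixels with value < t (dark targets).
#' @return Logical mask matrix.
#' @export
apply_threshold <- function(image8, t, polarity = c("above", "below")) {
  polarity <- match.arg(polarity)
  if (t < 0 || t > 255) stop("threshold must be in 0..255")
  img <- check_image8(image8)
  if (polarity == "above") img > t else img < t
}
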