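# Shared fixtures: everything is generated in code, deterministically.

# small, fast scene for unit tests
tiny_scene_cfg <- function(...) {
  args <- list(lines_per_bird_at_1bps = 80L, pixels_per_line = 80L,
               spot_radius_px = 6L, seed = 101L)
  override <- list(...)
  args[names(override)] <- override
  do.call(scene_config, args)
}

# random 256-bin histograms with at least two occupied bins
random_histogram <- function(rng) {
  n_modes <- sample(2:4, 1)
  h <- numeric(256)
  for (i in seq_len(n_modes)) {
    center <- sample(10:245, 1)
    width <- sample(3:25, 1)
    count <- sample(50:2000, 1)
    g <- round(rnorm(count, center, width))
    g <- g[g >= 0 & g <= 255]
    h <- h + tabulate(g + 1L, 256L)
  }
  if (sum(h > 0) < 2L) h[c(40, 200)] <- h[c(40, 200)] + 10
  as.integer(h)
}

# independent objective re-implementations used as exhaustive-scan oracles
shanbhag_objective <- function(h, t) {
  p <- h / sum(h)
  P1 <- cumsum(p); P2 <- 1 - P1
  if (P1[t + 1] <= 0 || P2[t + 1] <= 0) return(Inf)
  term <- 0.5 / P1[t + 1]
  eb <- 0
  for (g in seq_len(t)) eb <- eb - p[g + 1] * log(1 - term * P1[g])
  eb <- eb * term
  term <- 0.5 / P2[t + 1]
  eo <- 0
  for (g in (t + 1):255) eo <- eo - p[g + 1] * log(1 - term * P2[g + 1])
  eo <- eo * term
  abs(eb - eo)
}

huang_objective <- function(h, t) {
  nz <- which(h > 0)
  first <- nz[1] - 1; last <- nz[length(nz)] - 1
  if (t < first || t >= last) return(Inf)
  C <- last - first
  g <- 0:255
  S <- cumsum(h); W <- cumsum(h * g)
  smu <- function(d) {
    mu <- 1 / (1 + d / C)
    ifelse(d == 0, 0, -mu * log(mu) - (1 - mu) * log(1 - mu))
  }
  mu0 <- round(W[t + 1] / S[t + 1])
  mu1 <- round((W[last + 1] - W[t + 1]) / (S[last + 1] - S[t + 1]))
  i0 <- first:t; i1 <- (t + 1):last
  sum(smu(pmin(abs(i0 - mu0), C)) * h[i0 + 1]) +
    sum(smu(pmin(abs(i1 - mu1), C)) * h[i1 + 1])
}

# brute-force median filter: per-pixel sorted neighbourhood
naive_median_filter <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  r <- floor(radius)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- integer(0)
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 > radius^2) next
      y <- i + dy; x <- j + dx
      if (y >= 1 && y <= nr && x >= 1 && x <= nc) vals <- c(vals, img[y, x])
    }
    v <- sort(vals)
    n <- length(v)
    out[i, j] <- if (n %% 2 == 1) v[(n + 1) / 2] else
      as.integer(floor((v[n / 2] + v[n / 2 + 1] + 1) / 2))
  }
  out
}
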