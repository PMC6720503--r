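test_that("histogram equalization preserves rank order and flattens the CDF", {
  set.seed(61)
  img <- matrix(as.integer(pmin(pmax(round(rnorm(80 * 80, 120, 25)), 0), 255)),
                80, 80)
  eq <- hist_equalize(img, 0)
  # monotone mapping: rank order preserved exactly
  o <- order(as.vector(img))
  expect_true(all(diff(as.vector(eq)[o]) >= 0))
  lut_in <- sort(unique(as.vector(img)))
  lut_out <- vapply(lut_in, function(g) eq[which(img == g)[1]], 0L)
  expect_true(all(diff(lut_out) >= 0))
  # CDF flatness: cumulative histogram within 2% of linear (up to the
  # granularity of the largest single bin)
  h <- hist256(eq)
  cdf <- cumsum(h) / sum(h)
  dev <- abs(cdf - (0:255) / 255)[h > 0]
  expect_lt(max(dev) - max(h) / sum(h), 0.02)
})

test_that("equalization keeps two-level images distinct and ordered", {
  img <- matrix(10L, 50, 50)
  img[sample.int(2500, 250)] <- 200L
  eq <- hist_equalize(img, 0)
  lv <- sort(unique(as.vector(eq)))
  expect_length(lv, 2L)
  expect_lt(eq[img == 10][1], eq[img == 200][1])
  expect_equal(min(eq), 0L)                        # lowest occupied bin -> 0
})

test_that("sharpening is a flat-field-invariant unsharp kernel", {
  flat <- matrix(77L, 30, 30)
  expect_identical(sharpen(flat), flat)
  # kernel arithmetic on an interior impulse: center 12/4, neighbours -1/4
  img <- matrix(100L, 9, 9)
  img[5, 5] <- 140L
  sh <- sharpen(img)
  expect_equal(sh[5, 5], as.integer(round((12 * 140 - 8 * 100) / 4)))
  expect_equal(sh[4, 5], as.integer(round((12 * 100 - 7 * 100 - 140) / 4)))
})

test_that("the disc median filter matches a brute-force sorted-neighbourhood oracle", {
  flat <- matrix(42L, 20, 20)
  expect_identical(median_filter(flat, 2), flat)
  # single impulse on flat background is removed
  imp <- flat; imp[10, 10] <- 255L
  expect_identical(median_filter(imp, 2), flat)
  set.seed(62)
  img <- matrix(sample.int(256, 32 * 32, TRUE) - 1L, 32, 32)
  expect_identical(median_filter(img, 2), naive_median_filter(img, 2))
  expect_identical(median_filter(img, 3.5), naive_median_filter(img, 3.5))
  expect_error(median_filter(img, 0), "radius")
  # the radius-2 disc has exactly 13 pixels
  off <- expand.grid(dy = -2:2, dx = -2:2)
  expect_equal(sum(off$dy^2 + off$dx^2 <= 4), 13L)
})

test_that("auto-thresholds bracket bimodal histograms", {
  # two narrow modes centered at 50 and 200
  h <- integer(256)
  h[49:53] <- c(50L, 200L, 500L, 200L, 50L)
  h[199:203] <- c(40L, 160L, 400L, 160L, 40L)
  ts <- threshold_shanbhag(h)
  th <- threshold_huang(h)
  expect_true(ts > 50 && ts < 200)
  expect_true(th > 50 && th < 200)
  # the degenerate two-spike histogram still separates the modes
  h2 <- integer(256); h2[51] <- 500L; h2[201] <- 400L
  for (t in c(threshold_shanbhag(h2), threshold_huang(h2)))
    expect_true(t >= 50 && t < 200)
  single <- integer(256); single[100] <- 10L
  expect_error(threshold_shanbhag(single), "two")
  expect_error(threshold_huang(single), "two")
})

test_that("thresholds equal the exhaustive minimizer of their own objective", {
  set.seed(63)
  for (i in 1:30) {
    h <- random_histogram()
    nz <- which(h > 0)
    first <- nz[1] - 1L; last <- nz[length(nz)] - 1L
    cand <- first:last
    obj_s <- vapply(cand, function(t) shanbhag_objective(h, t), 0)
    expect_equal(threshold_shanbhag(h), cand[which.min(obj_s)])
    cand_h <- first:(last - 1L)
    obj_h <- vapply(cand_h, function(t) huang_objective(h, t), 0)
    expect_equal(threshold_huang(h), cand_h[which.min(obj_h)])
  }
})

test_that("Shanbhag thresholds mirror under histogram reflection", {
  set.seed(64)
  for (i in 1:10) {
    h <- integer(256)
    g <- c(round(rnorm(3000, 70, 12)), round(rnorm(1200, 190, 9)))
    g <- g[g >= 0 & g <= 255]
    h <- tabulate(g + 1L, 256L)
    t1 <- threshold_shanbhag(h)
    t2 <- threshold_shanbhag(rev(h))
    expect_lte(abs((255 - t1 - 1) - t2), 1L)       # tie tolerance
  }
})

test_that("Huang thresholds are translation-equivariant", {
  set.seed(65)
  for (i in 1:10) {
    h <- integer(256)
    h[31:80] <- sample.int(50, 50, TRUE)
    h[151:180] <- sample.int(80, 30, TRUE)
    t0 <- threshold_huang(h)
    for (shift in c(10L, 40L)) {
      hs <- integer(256)
      hs[(31:180) + shift] <- h[31:180]
      expect_equal(threshold_huang(hs), t0 + shift)
    }
  }
})

test_that("threshold masks shrink monotonically as the cut rises", {
  set.seed(66)
  img <- matrix(sample.int(256, 40 * 40, TRUE) - 1L, 40, 40)
  counts <- vapply(0:255, function(t) sum(apply_threshold(img, t, "above")), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(sum(apply_threshold(img, 255, "above")), 0L)
  expect_equal(sum(apply_threshold(img, 0, "above")), sum(img >= 1))
  expect_equal(apply_threshold(img, 100, "below"), img < 100)
})
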