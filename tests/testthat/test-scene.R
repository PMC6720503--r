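test_that("default wavelength axis covers 410-690 nm in 27 even bands", {
  wl <- default_wavelength_axis()
  expect_length(wl, 27L)
  expect_equal(wl[1], 410)
  expect_equal(wl[27], 690)
  expect_equal(unique(round(diff(wl), 10)), round(280 / 26, 10))
  expect_silent(validate_wavelength_axis(wl))
  expect_error(validate_wavelength_axis(rev(wl)), "increasing")
  expect_error(validate_wavelength_axis(seq(390, 690, length.out = 27)), "400 nm")
})

test_that("nearest band lookup stays in range and breaks ties low", {
  wl <- default_wavelength_axis()
  expect_equal(wl[nearest_band(wl, 630)], 410 + 20 * 280 / 26)
  expect_error(nearest_band(wl, 300), "outside")
  expect_equal(nearest_band(c(410, 420, 430), 415), 1L)  # exact tie goes low
})

test_that("skin spectrum has a 490 nm valley, a 515 nm rise and no peak beyond 500 nm", {
  wl <- default_wavelength_axis()
  cfg <- tiny_scene_cfg()
  s <- skin_spectrum(wl, cfg)
  expect_true(all(s > 0))
  expect_lt(s[nearest_band(wl, 490)], s[nearest_band(wl, 530)])
  win <- wl >= 500 & wl <= 680
  expect_lt(max(s[win]) / min(s[win]), 1.3)
  cfg0 <- cfg; cfg0$skin_level <- 0
  expect_equal(skin_spectrum(wl, cfg0), rep(0, 27))
})

test_that("fecal spectra peak in the porphyrin region with upper > bottom contrast", {
  wl <- default_wavelength_axis()
  cfg <- tiny_scene_cfg()
  up <- fecal_spectrum("upper", wl, cfg)
  bo <- fecal_spectrum("bottom", wl, cfg)
  sk <- skin_spectrum(wl, cfg)
  pk <- wl[which.max(up)]
  expect_true(pk >= 620 && pk <= 640)
  # zero amplitude degenerates to skin
  cfg0 <- cfg; cfg0$spot_amplitudes <- c(upper = 1e-12, bottom = 0.5e-12)
  expect_equal(fecal_spectrum("upper", wl, cfg0), sk, tolerance = 1e-9)
  # 630/600 contrast ordering: upper > bottom > skin
  r <- function(x) x[nearest_band(wl, 630)] / x[nearest_band(wl, 600)]
  expect_gt(r(up), r(bo))
  expect_gt(r(bo), r(sk))
  expect_error(fecal_spectrum("colon", wl, cfg))
})

test_that("rendered scenes are deterministic with 4 ground-truth spots per bird", {
  cfg <- tiny_scene_cfg()
  a <- render_scene(cfg)
  b <- render_scene(cfg)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(render_rgb(a), render_rgb(b))
  expect_length(a$truth$spots, 4L)
  expect_setequal(vapply(a$truth$spots, `[[`, "", "class"),
                  c("upper", "upper", "bottom", "bottom"))
  cfg3 <- tiny_scene_cfg(n_birds = 3L)
  expect_length(render_scene(cfg3)$truth$spots, 12L)
  # spots disjoint and inside the carcass
  acc <- matrix(0L, nrow(a$truth$skin_mask), ncol(a$truth$skin_mask))
  for (s in a$truth$spots) {
    acc <- acc + s$mask
    expect_true(all(a$truth$skin_mask[s$mask]))
  }
  expect_lte(max(acc), 1L)
})

test_that("conveyor speed decimates scan lines by integer division", {
  for (sp in c(1L, 3L, 5L)) {
    sc <- render_scene(tiny_scene_cfg(speed_bps = sp))
    expect_equal(dim(sc$cube$data)[1], 80L %/% sp)
  }
  expect_error(scene_config(speed_bps = 2L), "speed")
})

test_that("mean spectrum over each truth mask reproduces the generating spectrum", {
  cfg <- tiny_scene_cfg(n_birds = 2L)
  sc <- render_scene(cfg)
  # the per-band standard error is noise_sd / sqrt(n); over 8 spots x 27
  # bands nearly all deviations sit inside 3 standard errors and none far
  # beyond it
  z <- unlist(lapply(sc$truth$spots, function(s) {
    got <- vapply(seq_len(27), function(k) mean(sc$cube$data[, , k][s$mask]), 0)
    abs(got - s$expected_spectrum) / (cfg$noise_sd / sqrt(s$area_px))
  }))
  expect_gt(mean(z < 3), 0.99)
  expect_lt(max(z), 4)
  n_skin <- sum(sc$truth$skin_only_mask)
  got <- vapply(seq_len(27), function(k)
    mean(sc$cube$data[, , k][sc$truth$skin_only_mask]), 0)
  expect_lt(max(abs(got - sc$truth$expected_skin_spectrum)),
            3 * cfg$noise_sd / sqrt(n_skin))
})

test_that("classification accuracy is monotone in spot amplitude", {
  amp_levels <- list(c(upper = 0.3, bottom = 0.1),
                     c(upper = 1.0, bottom = 0.35),
                     c(upper = 3.0, bottom = 1.05))
  acc <- vapply(amp_levels, function(a) {
    sc <- render_scene(tiny_scene_cfg(n_birds = 2L, spot_amplitudes = a))
    ls <- labeled_spectra_from_truth(sc, n_per_class = 150L, seed = 7L)
    loo_cv(ls$X, ls$y, n_latent = 3L)$accuracy_balanced
  }, 0)
  expect_true(all(diff(acc) >= 0))
})

test_that("matching RGB image darkens fecal spots in the blue channel", {
  sc <- render_scene(tiny_scene_cfg())
  rgb <- render_rgb(sc)
  expect_true(all(rgb >= 0L & rgb <= 255L))
  expect_equal(dim(rgb)[3], 3L)
  blue <- rgb[, , 3]
  spot_mask <- Reduce(`|`, lapply(sc$truth$spots, `[[`, "mask"))
  skin_only <- sc$truth$skin_only_mask
  expect_lt(mean(blue[spot_mask]), mean(blue[skin_only]))
  # spotless variant: no pixels darker than the skin population floor
  sc0 <- sc
  sc0$truth$spots <- list()
  sc0$truth$skin_only_mask <- sc0$truth$skin_mask
  blue0 <- render_rgb(sc0)[, , 3]
  expect_gt(min(blue0[sc0$truth$skin_mask]), min(blue[spot_mask]))
  d <- density(blue0[sc0$truth$skin_mask])
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  expect_equal(sum(d$y[peaks] > 0.1 * max(d$y)), 1L)
})
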