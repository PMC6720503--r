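test_that("band ratios guard the denominator and self-ratio to one", {
  cube <- spectral_cube(array(5, c(8, 8, 27)))
  r <- band_ratio(cube, 630, 600)
  expect_true(all(r$data == 1))
  arr <- array(2, c(4, 4, 27))
  arr[1, 1, ] <- 0
  cube0 <- spectral_cube(arr)
  r0 <- band_ratio(cube0, 630, 600)
  expect_equal(r0$data[1, 1], 0)
  expect_true(attr(r0$data, "invalid")[1, 1])
  expect_false(any(attr(r0$data, "invalid")[-1, ]))
  expect_error(band_ratio(cube, 900, 600), "outside")
})

test_that("the 630/600 ratio orders upper > bottom > skin on synthetic scenes", {
  sc <- render_scene(tiny_scene_cfg(n_birds = 2L))
  r <- band_ratio(sc$cube, 630, 600)
  means <- vapply(c("upper", "bottom"), function(cl)
    mean(r$data[fecalspec:::class_union_mask(sc$truth, cl)]), 0)
  skin_mean <- mean(r$data[sc$truth$skin_only_mask])
  expect_gt(means[["upper"]], means[["bottom"]])
  expect_gt(means[["bottom"]], skin_mean)
})

test_that("630/600 separates upper from skin better than the alternative ratios", {
  sc <- render_scene(tiny_scene_cfg(n_birds = 2L))
  fisher <- vapply(list(c(630, 600), c(620, 600), c(512, 492)), function(p) {
    img <- band_ratio(sc$cube, p[1], p[2])$data
    a <- img[fecalspec:::class_union_mask(sc$truth, "upper")]
    b <- img[sc$truth$skin_only_mask]
    abs(mean(a) - mean(b)) / sqrt(var(a) + var(b))
  }, 0)
  expect_gt(fisher[1], fisher[2])
  expect_gt(fisher[1], fisher[3])
})

test_that("per-class ratio densities normalize and order their modes", {
  sc <- render_scene(tiny_scene_cfg(n_birds = 2L))
  r <- band_ratio(sc$cube, 630, 600)
  dens <- ratio_density_by_class(r, sc$truth)
  modes <- vapply(dens, function(d) d$x[which.max(d$y)], 0)
  expect_gt(modes[["upper"]], modes[["bottom"]])
  expect_gt(modes[["bottom"]], modes[["skin"]])
  for (d in dens) {
    mass <- sum(d$y) * mean(diff(d$x))
    expect_equal(mass, 1, tolerance = 1e-3)
  }
  # single-valued class degenerates to a spike at that value
  img1 <- r
  cls1 <- sc$truth$spots[[1]]$class
  img1$data[fecalspec:::class_union_mask(sc$truth, cls1)] <- 7
  d1 <- ratio_density_by_class(img1, sc$truth)
  expect_equal(d1[[cls1]]$x[which.max(d1[[cls1]]$y)], 7, tolerance = 1e-3)
})

test_that("PC score images equal row-wise projection of the flattened cube", {
  sc <- render_scene(tiny_scene_cfg())
  ls <- labeled_spectra_from_truth(sc, n_per_class = 100L, seed = 2L)
  m <- pca_fit(ls$X, 3)
  img <- pc_score_image(sc$cube, m, 2)
  flat <- pca_project(m, cube_to_matrix(sc$cube))[, 2]
  expect_equal(as.vector(img$data), as.vector(flat))
  expect_equal(img$provenance$params$component, 2L)
  # a cube equal to the model center everywhere scores zero
  d <- dim(sc$cube$data)
  cen <- spectral_cube(array(rep(m$center, each = d[1] * d[2]), d))
  img0 <- pc_score_image(cen, m, 1)
  expect_lt(max(abs(img0$data)), 1e-10)
  expect_error(pc_score_image(sc$cube, m, 9), "range")
})

test_that("spot scores dominate skin variation on the PC2 image", {
  sc <- render_scene(tiny_scene_cfg(n_birds = 2L))
  ls <- labeled_spectra_from_truth(sc, n_per_class = 200L, seed = 3L)
  m <- pca_fit(ls$X, 3)
  img <- pc_score_image(sc$cube, m, 2)
  spot_mask <- Reduce(`|`, lapply(sc$truth$spots, `[[`, "mask"))
  expect_gt(mean(abs(img$data[spot_mask])),
            2 * sd(img$data[sc$truth$skin_only_mask]))
})

test_that("beta projection images reproduce per-pixel PLS-DA predictions", {
  sc <- render_scene(tiny_scene_cfg())
  ls <- labeled_spectra_from_truth(sc, n_per_class = 120L, seed = 4L)
  m <- plsda_fit(ls$X, ls$y, n_latent = 3L)
  img <- beta_projection_image(sc$cube, m, "upper")
  pr <- predict(m, cube_to_matrix(sc$cube))
  expect_equal(as.vector(img$data), unname(pr$yhat[, "upper"]))
  expect_equal(as.vector(attr(img$data, "class_map")), pr$class)
  # a training upper spectrum predicts near one
  up_rows <- ls$X[ls$y == "upper", ]
  yh <- predict(m, colMeans(up_rows))$yhat[, "upper"]
  expect_gt(yh, 0.5)
  # binarized arg-max map recovers at least 3 of the 4 spots
  cm <- attr(img$data, "class_map")
  rep <- detect_spots(cm == "upper" | cm == "bottom", truth = sc$truth)
  expect_gte(rep$n_matched, 3L)
  expect_error(beta_projection_image(sc$cube, m, "feces"), "not among")
})

test_that("8-bit scaling is invertible and flags constant images", {
  set.seed(67)
  img <- matrix(runif(900, -2, 3), 30, 30)
  i8 <- to_8bit(img)
  expect_equal(min(i8), 0L); expect_equal(max(i8), 255L)
  rng <- attr(i8, "range")
  back <- rng[1] + (i8 / 255) * (rng[2] - rng[1])
  expect_lt(max(abs(back - img)), (rng[2] - rng[1]) / 255)
  expect_warning(z <- to_8bit(matrix(4, 5, 5)), "constant")
  expect_true(all(z == 0L))
  span <- matrix(c(0, 1), 2, 2)
  s8 <- to_8bit(span)
  expect_equal(range(s8), c(0L, 255L))
})
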