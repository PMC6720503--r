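test_that("MSC inverts affine scatter distortions exactly", {
  ref <- skin_spectrum()
  X <- rbind(ref, 2 * ref + 3, 0.5 * ref - 1)
  out <- msc(X, reference = ref)
  for (i in 1:3) expect_equal(unname(out[i, ]), unname(ref), tolerance = 1e-10)
})

test_that("MSC per-row coefficients match the normal-equations oracle", {
  set.seed(21)
  X <- matrix(rexp(50 * 27), 50, 27)
  ref <- colMeans(X)
  out <- msc(X)
  for (i in seq_len(nrow(X))) {
    fit <- lm.fit(cbind(1, ref), X[i, ])           # independent OLS oracle
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    expect_equal(unname(out[i, ]), unname((X[i, ] - a) / b), tolerance = 1e-10)
  }
})

test_that("MSC is idempotent under a fixed reference and flags constant rows", {
  set.seed(22)
  X <- matrix(runif(20 * 27, 1, 3), 20, 27)
  ref <- colMeans(X)
  once <- msc(X, ref)
  twice <- msc(once, ref)
  expect_equal(unname(twice), unname(once), tolerance = 1e-10)
  Xf <- rbind(X[1, ], rep(2, 27))
  out <- msc(Xf, ref)
  expect_equal(attr(out, "flagged"), 2L)
  expect_equal(unname(out[2, ]), rep(2, 27))       # returned uncorrected
})

test_that("Savitzky-Golay reproduces polynomials exactly", {
  k <- 0:26
  expect_equal(savgol(rep(5, 27), 5, 2, 1), rep(0, 27))       # constant -> 0
  expect_equal(savgol(k^2, 5, 2, 2), rep(2, 27))              # quadratic -> 2
  expect_equal(savgol(k^2, 5, 2, 1), 2 * k)                   # exact derivative
  # smoothing (deriv 0) reproduces any degree-<=polyorder polynomial row
  row <- 3 - 0.5 * k + 0.02 * k^2
  expect_equal(savgol(row, 7, 2, 0), row, tolerance = 1e-10)
  expect_error(savgol(row, 4, 2, 1), "odd")
  expect_error(savgol(row, 5, 5, 1), "polyorder")
  expect_error(savgol(row, 5, 2, 3), "deriv")
})

test_that("Savitzky-Golay derivative matches finite differences of an oversampled oracle", {
  k <- 0:26
  h <- 1e-4                                        # oversampled central differences
  interior <- 3:25
  # a slowly varying Gaussian is reproduced to 1e-3 relative
  f <- function(t) exp(-((t - 13) / 60)^2)
  d1 <- savgol(f(k), 5, 2, 1)
  oracle <- (f(k + h) - f(k - h)) / (2 * h)
  expect_lt(max(abs(d1[interior] - oracle[interior])) / max(abs(oracle)), 1e-3)
  # a sharper peak keeps the usual local-quadratic bias
  g <- function(t) exp(-((t - 13) / 7)^2)
  d1g <- savgol(g(k), 5, 2, 1)
  oracleg <- (g(k + h) - g(k - h)) / (2 * h)
  expect_lt(max(abs(d1g[interior] - oracleg[interior])) / max(abs(oracleg)), 0.06)
})

test_that("Savitzky-Golay interior values agree with the reference filter", {
  skip_if_not_installed("signal")
  set.seed(23)
  X <- matrix(runif(10 * 27), 10, 27)
  for (deriv in 0:2) {
    ours <- savgol(X, 5, 2, deriv)
    for (i in seq_len(nrow(X))) {
      ref <- signal::sgolayfilt(X[i, ], p = 2, n = 5, m = deriv)
      expect_equal(ours[i, 3:25], ref[3:25], tolerance = 1e-10)
    }
  }
})

test_that("preprocessing transforms are fitted on training data only", {
  set.seed(24)
  Xtr <- matrix(runif(30 * 27, 1, 2), 30, 27)
  fit <- prep_fit(Xtr, prep_config("msc"))
  expect_equal(fit$reference, colMeans(Xtr))
  xnew <- 2 * colMeans(Xtr) + 1
  out <- prep_apply(fit, xnew)
  expect_equal(unname(out), unname(colMeans(Xtr)), tolerance = 1e-10)
  # derivative methods are stateless per row
  fit1 <- prep_fit(Xtr, prep_config("d1"))
  expect_equal(prep_apply(fit1, Xtr[3, ]), savgol(Xtr[3, ], 5, 2, 1))
})

test_that("per-class summaries match a naive two-pass oracle", {
  sc <- render_scene(tiny_scene_cfg())
  ls <- labeled_spectra_from_truth(sc, n_per_class = 80L, seed = 3L)
  cs <- class_mean_sd(ls)
  for (cl in names(cs)) {
    rows <- ls$X[ls$y == cl, , drop = FALSE]
    mu <- colSums(rows) / nrow(rows)
    s2 <- colSums(sweep(rows, 2, mu)^2) / (nrow(rows) - 1)
    expect_equal(cs[[cl]]$mean, mu, tolerance = 1e-12)
    expect_equal(cs[[cl]]$sd, sqrt(s2), tolerance = 1e-12)
  }
  # upper mean spectrum peaks in the porphyrin window
  wl <- attr(cs, "axis")
  pk <- wl[which.max(cs$upper$mean)]
  expect_true(pk >= 620 && pk <= 640)
  # two identical rows -> zero sd
  two <- structure(list(X = rbind(ls$X[1, ], ls$X[1, ]), y = c("a", "a"),
                        axis = ls$axis), class = "labeled_spectra")
  expect_equal(class_mean_sd(two)$a$sd, rep(0, 27))
  one <- structure(list(X = ls$X[1, , drop = FALSE], y = "a", axis = ls$axis),
                   class = "labeled_spectra")
  expect_error(class_mean_sd(one), "fewer than 2")
})
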