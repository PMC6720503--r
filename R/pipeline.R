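#' Study configuration for the three analysis tracks
#'
#' Describes a full simulated study: for each conveyor speed (1, 3, 5
#' birds/s) there are `replicas` scene replicas of `birds_per_sample` birds;
#' `calibration_fraction` of the replicas (rounded, at least one left for
#' validation) are used for model fitting and the rest for validation, the
#' 2-of-3 split generalized.  The on-line validation pool used for spot
#' detection (`validation_birds`) holds 10 birds split 4/3/3 across the
#' speeds — 40 ground-truth spots, the size of the on-line evaluation the
#' pipeline's headline detection accuracy refers to.
#'
#' @param speeds subset of `c(1, 3, 5)`.
#' @param replicas replicas per speed (default 3).
#' @param birds_per_sample birds per calibration scene (default 10).
#' @param calibration_fraction fraction of replicas used for calibration.
#' @param validation_birds named integer vector: birds in the validation
#'   scene at each speed.
#' @param n_per_class pixels sampled per class for spectral analysis.
#' @param n_latent PLS-DA latent variables.
#' @param n_pc principal components fitted for the image track.
#' @param prep_methods preprocessing methods compared in the spectral track.
#' @param seed master seed; all scene and sampling seeds derive from it.
#' @param scene named list of overrides passed to [scene_config()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(speeds = c(1L, 3L, 5L), replicas = 3L,
                         birds_per_sample = 10L,
                         calibration_fraction = 2 / 3,
                         validation_birds = c(`1` = 4L, `3` = 3L, `5` = 3L),
                         n_per_class = 600L, n_latent = 3L, n_pc = 4L,
                         prep_methods = c("none", "msc", "d1", "d2"),
                         seed = 42L, scene = list()) {
  if (!all(speeds %in% c(1L, 3L, 5L))) stop("speeds must be within {1, 3, 5}")
  if (replicas < 1L) stop("replicas must be >= 1")
  n_cal <- max(1L, round(replicas * calibration_fraction))
  if (replicas > 1L && n_cal >= replicas) n_cal <- replicas - 1L
  structure(list(speeds = as.integer(speeds), replicas = as.integer(replicas),
                 birds_per_sample = as.integer(birds_per_sample),
                 calibration_fraction = calibration_fraction,
                 n_calibration = n_cal,
                 validation_birds = validation_birds,
                 n_per_class = as.integer(n_per_class),
                 n_latent = as.integer(n_latent), n_pc = as.integer(n_pc),
                 prep_methods = prep_methods,
                 seed = as.integer(seed), scene = scene),
            class = "study_config")
}

# deterministic per-scene seed, kept well below 2^31
scene_seed <- function(config, speed, replica, salt = 0L) {
  (config$seed %% 100000L) * 10000L + speed * 1000L + replica * 10L + salt
}

make_cfg <- function(config, speed, replica, n_birds, salt = 0L) {
  args <- c(list(speed_bps = speed, n_birds = n_birds,
                 seed = scene_seed(config, speed, replica, salt)),
            config$scene)
  do.call(scene_config, args[!duplicated(names(args))])
}

calibration_spectra <- function(config) {
  parts <- list()
  for (speed in config$speeds) {
    for (rep_i in seq_len(config$n_calibration)) {
      sc <- render_scene(make_cfg(config, speed, rep_i,
                                  config$birds_per_sample))
      n_each <- ceiling(config$n_per_class /
                          (length(config$speeds) * config$n_calibration))
      parts[[length(parts) + 1L]] <-
        labeled_spectra_from_truth(sc, n_per_class = n_each,
                                   seed = scene_seed(config, speed, rep_i, 9L))
    }
  }
  structure(list(X = do.call(rbind, lapply(parts, `[[`, "X")),
                 y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
                 provenance = do.call(rbind, lapply(parts, `[[`, "provenance")),
                 axis = parts[[1L]]$axis),
            class = "labeled_spectra")
}

#' Spectral analysis track (calibration spectra, PCA, PLS-DA comparison)
#'
#' Generates the calibration scenes, extracts labeled pixel spectra
#' (`n_per_class` per class pooled over calibration scenes), fits a PCA for
#' score-plot inspection, and runs leave-one-out cross-validated PLS-DA
#' under each configured preprocessing method.  The result table has one
#' row per preprocessing method with per-class sensitivity, balanced
#' accuracy and kappa.
#'
#' @param config a [study_config()].
#' @return List of class `case1_report`: `table` (data.frame), `metrics`
#'   (list of `mfi_metrics` per preprocessing method), `pca`, `plsda` (the
#'   no-preprocessing model), `spectra`, `class_summary`, `config`.
#' @export
run_case1 <- function(config = study_config()) {
  spectra <- calibration_spectra(config)
  if (length(unique(spectra$y)) < 2L)
    stop("spectral analysis needs at least two classes")
  pca <- pca_fit(spectra$X, A = config$n_pc)
  metrics <- list()
  rows <- list()
  for (m in config$prep_methods) {
    mt <- loo_cv(spectra$X, spectra$y, n_latent = config$n_latent,
                 prep = prep_config(m))
    metrics[[m]] <- mt
    sens <- setNames(mt$per_class$sensitivity, mt$per_class$class)
    rows[[m]] <- data.frame(prep = m,
                            bottom = sens[["bottom"]],
                            upper = sens[["upper"]],
                            skin = sens[["skin"]],
                            accuracy = mt$accuracy_balanced,
                            kappa = mt$kappa)
  }
  plsda <- plsda_fit(spectra$X, spectra$y, n_latent = config$n_latent,
                     prep = prep_config("none"))
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 metrics = metrics, pca = pca, plsda = plsda,
                 spectra = spectra, class_summary = class_mean_sd(spectra),
                 config = config),
            class = "case1_report")
}

#' @export
print.case1_report <- function(x, ...) {
  cat("Spectral classification (LOO cross-validated PLS-DA)\n")
  tab <- x$table
  for (cn in c("bottom", "upper", "skin", "accuracy"))
    tab[[cn]] <- sprintf("%.1f%%", 100 * tab[[cn]])
  tab$kappa <- sprintf("%.2f", x$table$kappa)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Chemical-image classification track
#'
#' Fits a PCA on pixel spectra subsampled from the calibration scenes
#' (foreground and background alike, as an unsupervised image decomposition)
#' and evaluates spot detection on held-out validation scenes at every
#' configured speed: the PC score image of `component` is scaled to 8 bits,
#' auto-thresholded with Huang's fuzzy method, and 8-connected components
#' are matched against ground truth.  PLS-DA beta-projection images and
#' 630/600 band-ratio images are produced for the same validation cubes for
#' comparison.  Validation scenes use replica index `replicas` (never seen
#' by calibration) — calibration cubes therefore never touch validation.
#'
#' @param config a [study_config()].
#' @param case1 optional `case1_report` supplying the PLS-DA model;
#'   computed internally when missing (only the model, not the full report).
#' @param component PC used for the score image (default 2).
#' @return List of class `case2_report`: per-cube results (`speed`,
#'   `threshold`, `report`s for pc/beta/ratio), `pooled_detection_accuracy`
#'   (PC-image track), `n_truth_total`, `pca_image`, `config`.
#' @export
run_case2 <- function(config = study_config(), case1 = NULL, component = 2L) {
  # unsupervised PCA on whole-image pixel spectra from calibration scenes
  pix <- list()
  for (speed in config$speeds) {
    sc <- render_scene(make_cfg(config, speed, 1L, config$birds_per_sample))
    M <- cube_to_matrix(sc$cube)
    step <- max(1L, floor(nrow(M) / 8000))
    pix[[as.character(speed)]] <- M[seq(1L, nrow(M), by = step), , drop = FALSE]
  }
  pca_img <- pca_fit(do.call(rbind, pix), A = max(config$n_pc, component))

  plsda <- if (!is.null(case1)) case1$plsda else {
    spectra <- calibration_spectra(config)
    plsda_fit(spectra$X, spectra$y, n_latent = config$n_latent,
              prep = prep_config("none"))
  }

  results <- list()
  n_matched <- 0L; n_truth <- 0L
  val_rep <- config$replicas                  # held-out replica index
  for (speed in config$speeds) {
    nb <- config$validation_birds[[as.character(speed)]]
    if (is.null(nb) || nb < 1L) next
    sc <- render_scene(make_cfg(config, speed, val_rep, nb, salt = 5L))
    pc_img <- pc_score_image(sc$cube, pca_img, component)
    img8 <- to_8bit(pc_img)
    t_huang <- threshold_huang(hist256(img8))
    mask <- apply_threshold(img8, t_huang, "above")
    rep_pc <- detect_spots(mask, truth = sc$truth)

    beta_img <- beta_projection_image(sc$cube, plsda, "upper")
    cm <- attr(beta_img$data, "class_map")
    beta_mask <- cm == "upper" | cm == "bottom"
    rep_beta <- detect_spots(beta_mask, truth = sc$truth)

    ratio_img <- band_ratio(sc$cube, 630, 600)
    r8 <- to_8bit(ratio_img)
    t_r <- threshold_huang(hist256(r8))
    rep_ratio <- detect_spots(apply_threshold(r8, t_r, "above"),
                              truth = sc$truth)

    n_matched <- n_matched + rep_pc$n_matched
    n_truth <- n_truth + rep_pc$n_truth
    results[[as.character(speed)]] <-
      list(speed = speed, n_birds = nb, huang_threshold = t_huang,
           ratio_threshold = t_r, pc = rep_pc, beta = rep_beta,
           ratio = rep_ratio)
  }
  structure(list(results = results,
                 pooled_detection_accuracy = n_matched / n_truth,
                 n_matched_total = n_matched, n_truth_total = n_truth,
                 pc_component = component, pca_image = pca_img,
                 config = config),
            class = "case2_report")
}

#' @export
print.case2_report <- function(x, ...) {
  cat(sprintf("Chemical-image classification (PC%d + Huang threshold)\n",
              x$pc_component))
  for (r in x$results)
    cat(sprintf("  %d bird/s: threshold %d, matched %d/%d, FP px %d\n",
                r$speed, r$huang_threshold, r$pc$n_matched, r$pc$n_truth,
                r$pc$false_positive_px))
  cat(sprintf("pooled detection accuracy: %d/%d = %.3f\n",
              x$n_matched_total, x$n_truth_total,
              x$pooled_detection_accuracy))
  invisible(x)
}

#' Color-image classification track
#'
#' Runs the blue-channel pipeline ([blue_channel_pipeline()]) on a batch of
#' synthetic color images (one bird each) and pools spot detection over the
#' batch.  Both the Shanbhag auto-threshold and the applied threshold
#' (default override 1, the revised value that suppresses false-positive
#' pixels) are recorded per image.
#'
#' @param config a [study_config()].
#' @param n_images batch size (default 29).
#' @param threshold_override threshold applied (default 1); `NULL` for the
#'   auto-threshold.
#' @return List of class `case3_report`: per-image results,
#'   `pooled_accuracy`, `n_matched_total`, `n_truth_total`, thresholds used,
#'   `config`.
#' @export
run_case3 <- function(config = study_config(), n_images = 29L,
                      threshold_override = 1L) {
  results <- list()
  n_matched <- 0L; n_truth <- 0L
  for (i in seq_len(n_images)) {
    sc <- simulate_scene(make_cfg(config, 1L, i, 1L, salt = 7L))
    out <- blue_channel_pipeline(sc$rgb, truth = sc$truth,
                                 threshold_override = threshold_override)
    n_matched <- n_matched + out$report$n_matched
    n_truth <- n_truth + out$report$n_truth
    results[[i]] <- list(image = i, threshold = out$threshold,
                         auto_threshold = out$auto_threshold,
                         n_matched = out$report$n_matched,
                         n_truth = out$report$n_truth,
                         false_positive_px = out$report$false_positive_px)
  }
  structure(list(results = results,
                 pooled_accuracy = if (n_truth > 0) n_matched / n_truth else 0,
                 n_matched_total = n_matched, n_truth_total = n_truth,
                 threshold_override = threshold_override,
                 config = config),
            class = "case3_report")
}

#' @export
print.case3_report <- function(x, ...) {
  cat(sprintf("Color-image classification: %d image(s), threshold %s\n",
              length(x$results),
              if (is.null(x$threshold_override)) "auto" else x$threshold_override))
  cat(sprintf("pooled detection accuracy: %d/%d = %.3f\n",
              x$n_matched_total, x$n_truth_total, x$pooled_accuracy))
  invisible(x)
}

#' Bundle analysis reports into JSON (and optional figures)
#'
#' Collects any of the three track reports into a single JSON bundle with
#' the configuration echo, seeds and thresholds (an audit trail), plus
#' optional PNG figures (mean spectra, PC score plot, ratio density).
#' Figures are renderings only, never inputs to computation; regenerating a
#' bundle from the same reports is idempotent.
#'
#' @param ... named reports (`case1`, `case2`, `case3`).
#' @param out_dir output directory (created if needed).
#' @param figures render PNG figures as well?
#' @return Path of the JSON bundle, invisibly.
#' @export
make_report <- function(..., out_dir, figures = FALSE) {
  reports <- list(...)
  if (!length(reports)) stop("supply at least one report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(package_version = as.character(utils::packageVersion("fecalspec")))
  for (nm in names(reports)) {
    r <- reports[[nm]]
    bundle$config <- unclass(r$config)
    if (inherits(r, "case1_report")) {
      bundle$case1 <- list(table = r$table,
                           confusions = lapply(r$metrics, `[[`, "confusion"))
    } else if (inherits(r, "case2_report")) {
      bundle$case2 <- list(
        pooled_detection_accuracy = r$pooled_detection_accuracy,
        n_matched = r$n_matched_total, n_truth = r$n_truth_total,
        per_speed = lapply(r$results, function(s) list(
          speed = s$speed, huang_threshold = s$huang_threshold,
          ratio_threshold = s$ratio_threshold,
          matched = s$pc$n_matched, truth = s$pc$n_truth,
          false_positive_px = s$pc$false_positive_px)))
    } else if (inherits(r, "case3_report")) {
      bundle$case3 <- list(pooled_accuracy = r$pooled_accuracy,
                           threshold_override = r$threshold_override,
                           per_image = r$results)
    }
  }
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  if (figures && !is.null(reports$case1)) {
    r <- reports$case1
    png(file.path(out_dir, "mean_spectra.png"), 700, 500)
    cs <- r$class_summary
    axis_nm <- attr(cs, "axis")
    cols <- c(upper = "red", bottom = "blue", skin = "darkgreen")
    plot(axis_nm, cs[[1]]$mean, type = "n", xlab = "wavelength (nm)",
         ylab = "fluorescence (a.u.)",
         ylim = range(unlist(lapply(cs, function(z) z$mean + z$sd)), 0))
    for (cl in names(cs)) {
      lines(axis_nm, cs[[cl]]$mean, col = cols[[cl]], lwd = 2)
      lines(axis_nm, cs[[cl]]$mean + cs[[cl]]$sd, col = cols[[cl]], lty = 3)
      lines(axis_nm, cs[[cl]]$mean - cs[[cl]]$sd, col = cols[[cl]], lty = 3)
    }
    legend("topleft", legend = names(cs), col = cols[names(cs)], lwd = 2)
    dev.off()
    png(file.path(out_dir, "pc_scores.png"), 600, 600)
    plot(r$pca, comps = c(2L, 3L), labels = r$spectra$y)
    dev.off()
  }
  invisible(json_path)
}
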