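#' Detect and evaluate spot candidates in a binary mask
#'
#' Labels the mask into 8-connected components, discards components smaller
#' than `min_area_px`, and — when ground truth is supplied — matches truth
#' spots to detections: a truth spot counts as detected when some single
#' component covers at least `match_frac` of the truth spot's area.  The
#' detection accuracy is matched truth spots over total truth spots;
#' `false_positive_px` counts mask pixels outside all truth spots.
#'
#' @param mask logical matrix.
#' @param min_area_px smallest component kept (default 5, suppressing
#'   single-pixel noise).
#' @param truth optional ground truth from [render_scene()].
#' @param match_frac required truth-area containment fraction (default 0.5).
#' @return An object of class `spot_report`: `detected` (data.frame with
#'   centroid_line, centroid_pixel (0-based), area_px and bounding box),
#'   `n_detected`, and when truth is given `n_truth`, `n_matched`, `matched`
#'   (per-truth-spot logical + matched component id), `detection_accuracy`,
#'   `false_positive_px`.
#' @export
detect_spots <- function(mask, min_area_px = 5L, truth = NULL,
                         match_frac = 0.5) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- label8_cpp(mask)
  n_raw <- max(lab)
  keep <- integer(0)
  detected <- data.frame(centroid_line = numeric(0), centroid_pixel = numeric(0),
                         area_px = integer(0), line0 = integer(0),
                         pixel0 = integer(0), line1 = integer(0),
                         pixel1 = integer(0))
  if (n_raw > 0) {
    areas <- tabulate(lab[lab > 0], n_raw)
    keep <- which(areas >= min_area_px)
    rows <- lapply(keep, function(id) {
      idx <- which(lab == id, arr.ind = TRUE)
      data.frame(centroid_line = mean(idx[, 1]) - 1,
                 centroid_pixel = mean(idx[, 2]) - 1,
                 area_px = nrow(idx),
                 line0 = min(idx[, 1]) - 1L, pixel0 = min(idx[, 2]) - 1L,
                 line1 = max(idx[, 1]), pixel1 = max(idx[, 2]))
    })
    if (length(rows)) detected <- do.call(rbind, rows)
  }
  out <- list(detected = detected, n_detected = nrow(detected),
              min_area_px = min_area_px)
  if (!is.null(truth)) {
    n_truth <- length(truth$spots)
    matched <- logical(n_truth)
    match_id <- rep(NA_integer_, n_truth)
    for (i in seq_len(n_truth)) {
      tm <- truth$spots[[i]]$mask
      ids <- lab[tm]
      ids <- ids[ids > 0 & ids %in% keep]
      if (length(ids)) {
        ov <- sort(table(ids), decreasing = TRUE)
        if (ov[1L] >= match_frac * sum(tm)) {
          matched[i] <- TRUE
          match_id[i] <- as.integer(names(ov)[1L])
        }
      }
    }
    truth_union <- matrix(FALSE, nrow(mask), ncol(mask))
    for (s in truth$spots) truth_union <- truth_union | s$mask
    kept_mask <- matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
    out$n_truth <- n_truth
    out$n_matched <- sum(matched)
    out$matched <- data.frame(spot = seq_len(n_truth),
                              class = vapply(truth$spots, `[[`, "", "class"),
                              matched = matched, component = match_id)
    out$detection_accuracy <- if (n_truth > 0) sum(matched) / n_truth else NA_real_
    out$false_positive_px <- sum(kept_mask & !truth_union)
  }
  structure(out, class = "spot_report")
}

#' @export
print.spot_report <- function(x, ...) {
  cat(sprintf("Spot report: %d component(s) >= %d px\n",
              x$n_detected, x$min_area_px))
  if (!is.null(x$n_truth))
    cat(sprintf("  matched %d / %d truth spots (accuracy %.3f), %d false-positive px\n",
                x$n_matched, x$n_truth, x$detection_accuracy,
                x$false_positive_px))
  invisible(x)
}

#' Paint a detection mask over a grayscale base image
#'
#' @param base_image numeric matrix (rendered to 8-bit grayscale if needed)
#'   or 8-bit matrix.
#' @param mask logical matrix, same shape.
#' @param color length-3 RGB vector in 0..255.
#' @return Integer array rows x cols x 3 in 0..255.
#' @export
pseudocolor_overlay <- function(base_image, mask, color = c(255L, 0L, 0L)) {
  base <- if (inherits(base_image, "chemical_image")) base_image$data else base_image
  if (!identical(dim(base)[1:2], dim(mask)))
    stop("base image and mask shapes differ")
  if (any(base < 0) || any(base > 255) || any(base != round(base)))
    base <- suppressWarnings(to_8bit(base))
  out <- array(0L, c(nrow(base), ncol(base), 3L))
  for (ch in 1:3) {
    plane <- base
    plane[mask] <- color[ch]
    out[, , ch] <- as.integer(plane)
  }
  out
}

#' Color-image (blue channel) classification pipeline
#'
#' The color-image analysis track: take the blue channel of an 8-bit RGB
#' image (fecal spots are darkest there), enhance it with histogram
#' equalization (0.3% saturation), sharpening, and a radius-2.0 disc median
#' filter, then threshold.  The threshold defaults to the Shanbhag
#' auto-threshold of the enhanced image with polarity "below" (dark
#' targets); an override (e.g. the revised value 1, which trades recall for
#' far fewer false-positive pixels) may be supplied.  Detected components
#' are evaluated against ground truth when given.
#'
#' @param rgb integer array rows x cols x 3 with values 0..255.
#' @param truth optional ground truth from [render_scene()].
#' @param threshold_override integer threshold to use instead of the
#'   auto-threshold, or `NULL`.
#' @param min_area_px smallest component kept.
#' @return List with `mask`, `report` (a `spot_report`), `threshold` (the
#'   value applied), `auto_threshold` (Shanbhag value, always computed) and
#'   `enhanced` (the processed blue channel).
#' @export
blue_channel_pipeline <- function(rgb, truth = NULL, threshold_override = NULL,
                                  min_area_px = 5L) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("expected an RGB array (rows x cols x 3)")
  blue <- check_image8(rgb[, , 3L])
  enh <- median_filter(sharpen(hist_equalize(blue, 0.3)), 2.0)
  auto_t <- threshold_shanbhag(hist256(enh))
  t <- if (is.null(threshold_override)) auto_t else as.integer(threshold_override)
  mask <- apply_threshold(enh, t, "below")
  report <- detect_spots(mask, min_area_px = min_area_px, truth = truth)
  list(mask = mask, report = report, threshold = t, auto_threshold = auto_t,
       enhanced = enh)
}
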