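#' Write a spectral cube to disk
#'
#' The canonical on-disk format is the ENVI-style header/raster pair that
#' push-broom instruments commonly produce: a plain-text `.hdr` file holding
#' dimensions, interleave and the band-center wavelengths, next to a raw
#' little-endian float32 raster.  `BSQ` (band-sequential) and `BIL`
#' (band-interleaved-by-line) layouts are supported.  A multi-page TIFF
#' dialect is also available: one float32 page per band, scaled into [0, 1]
#' by the recorded data maximum, with wavelengths and scale in a JSON
#' sidecar (`<path>.json`).
#'
#' Because rasters are stored as float32, a write/read round trip is exact at
#' float32 precision: reading back and re-writing reproduces the file
#' bit-identically.
#'
#' @param cube a [spectral_cube()].
#' @param path output path; for ENVI this is the raster path (header written
#'   at `<path>.hdr`), for TIFF a `.tif` path.
#' @param format `"envi"` or `"tiff"`.
#' @param interleave `"bsq"` or `"bil"` (ENVI only).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "tiff"),
                       interleave = c("bsq", "bil")) {
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  if (format == "envi") {
    hdr <- c("ENVI",
             "description = {fecalspec spectral cube}",
             sprintf("samples = %d", d[2]),
             sprintf("lines = %d", d[1]),
             sprintf("bands = %d", d[3]),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 4",
             sprintf("interleave = %s", interleave),
             "byte order = 0",
             "wavelength units = Nanometers",
             sprintf("wavelength = {%s}",
                     paste(format(cube$axis, trim = TRUE, digits = 10),
                           collapse = ", ")))
    if (!is.null(cube$meta$speed_bps))
      hdr <- c(hdr, sprintf("speed bps = %d", cube$meta$speed_bps))
    writeLines(hdr, paste0(path, ".hdr"))
    # array is lines x samples x bands; writeBin wants a flat vector in
    # file order (innermost = samples)
    v <- if (interleave == "bsq") {
      aperm(cube$data, c(2, 1, 3))        # samples, lines, bands
    } else {
      aperm(cube$data, c(2, 3, 1))        # samples, bands, lines
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  } else {
    mx <- max(cube$data, 1e-12)
    pages <- lapply(seq_len(d[3]), function(k) cube$data[, , k] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(
      list(wavelength = cube$axis, scale = mx, speed_bps = cube$meta$speed_bps),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a spectral cube from disk
#'
#' Counterpart of [write_cube()]; the format is inferred from the file
#' extension (`.tif`/`.tiff` versus ENVI raster with `.hdr` sibling).
#' The header's wavelength list must match the raster band count and all
#' values must be non-negative, otherwise reading fails with a diagnostic.
#'
#' @param path path given to [write_cube()].
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("missing TIFF metadata sidecar: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    wl <- as.numeric(meta$wavelength)
    if (length(wl) != length(pages))
      stop(sprintf("sidecar lists %d wavelengths but TIFF has %d pages",
                   length(wl), length(pages)))
    d1 <- dim(pages[[1]])
    data <- array(0, c(d1[1], d1[2], length(pages)))
    for (k in seq_along(pages)) data[, , k] <- pages[[k]] * meta$scale
    return(spectral_cube(data, wl, meta = list(speed_bps = meta$speed_bps)))
  }
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  hdr <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "interleave", "wavelength")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf("header lists %d wavelengths but declares %d bands",
                 length(wl), nb))
  if (!identical(hdr[["data type"]], "4"))
    stop("only float32 rasters (ENVI data type 4) are supported")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = ns * nl * nb, size = 4L, endian = "little")
  if (length(v) != ns * nl * nb) stop("raster shorter than header declares")
  data <- switch(tolower(hdr$interleave),
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    stop("unsupported interleave: ", hdr$interleave))
  if (any(data < 0))
    stop("raster contains negative values; fluorescence cubes must be non-negative")
  meta <- list()
  if (!is.null(hdr[["speed bps"]])) meta$speed_bps <- as.integer(hdr[["speed bps"]])
  spectral_cube(data, wl, meta)
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); key <- NULL; buf <- NULL
  for (ln in lines) {
    if (!is.null(key)) {                  # inside a { } block
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) {
        out[[key]] <- gsub("[{}]", "", buf)
        key <- NULL; buf <- NULL
      }
      next
    }
    if (!grepl("=", ln)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    k <- trimws(kv[1]); v <- trimws(paste(kv[-1], collapse = "="))
    if (grepl("\\{", v) && !grepl("\\}", v)) { key <- k; buf <- v; next }
    out[[k]] <- gsub("[{}]", "", v)
  }
  out
}

#' Define a set of rectangular regions of interest
#'
#' ROIs are axis-aligned rectangles in the 0-based, half-open convention
#' `[line0, line1) x [pixel0, pixel1)` (the same convention masks and spot
#' reports use), each tagged with a spot class: `"upper"` (ceca/colon
#' spots), `"bottom"` (small intestine/duodenum spots) or `"skin"`.
#'
#' @param labels character vector of ROI names.
#' @param rects integer matrix with one row per ROI and columns
#'   `line0, pixel0, line1, pixel1`.
#' @param classes character vector of classes, one per ROI.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, rects, classes) {
  rects <- matrix(as.integer(rects), ncol = 4,
                  dimnames = list(labels, c("line0", "pixel0", "line1", "pixel1")))
  if (length(labels) != nrow(rects) || length(classes) != nrow(rects))
    stop("labels, rects and classes must agree in length")
  if (!all(classes %in% c("upper", "bottom", "skin")))
    stop("ROI classes must be upper, bottom or skin")
  if (any(rects[, "line1"] <= rects[, "line0"]) ||
      any(rects[, "pixel1"] <= rects[, "pixel0"]))
    stop("ROI rectangles must be non-empty (half-open, end > start)")
  if (any(rects < 0)) stop("ROI coordinates are 0-based and must be >= 0")
  structure(list(labels = labels, rects = rects, classes = classes),
            class = "roi_set")
}

#' Read / write ROI sets as JSON
#'
#' @param rois a [roi_set()].
#' @param path JSON file path.
#' @return `read_roi_json` returns a [roi_set()]; `write_roi_json` returns
#'   `path` invisibly.
#' @export
write_roi_json <- function(rois, path) {
  obj <- lapply(seq_along(rois$labels), function(i) list(
    label = rois$labels[i], class = rois$classes[i],
    rect = as.integer(rois$rects[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  roi_set(labels = vapply(obj, `[[`, "", "label"),
          rects = do.call(rbind, lapply(obj, function(o) unlist(o$rect))),
          classes = vapply(obj, `[[`, "", "class"))
}

#' Extract labeled pixel spectra from ROIs
#'
#' Pulls one spectrum per pixel inside each ROI rectangle and labels it with
#' the ROI's class, producing the N x K matrix that the chemometric models
#' consume.  Following the acquisition protocol this package models, each ROI
#' is expected to contribute between 480 and 700 pixels; counts outside that
#' range trigger a warning (not an error).
#'
#' @param cube a [spectral_cube()].
#' @param rois a [roi_set()]; rectangles must lie within the cube bounds.
#' @return A list of class `labeled_spectra`: `X` (N x K matrix), `y`
#'   (character class per row), `provenance` (data.frame with roi label,
#'   line, pixel per row) and `axis`.
#' @export
extract_roi_spectra <- function(cube, rois) {
  d <- dim(cube$data)
  Xs <- list(); ys <- list(); prov <- list()
  for (i in seq_along(rois$labels)) {
    r <- rois$rects[i, ]
    if (r["line1"] > d[1] || r["pixel1"] > d[2])
      stop(sprintf("ROI '%s' extends outside the cube (%d x %d)",
                   rois$labels[i], d[1], d[2]))
    li <- (r["line0"] + 1L):r["line1"]
    pi <- (r["pixel0"] + 1L):r["pixel1"]
    n <- length(li) * length(pi)
    if (n < 480L || n > 700L)
      warning(sprintf("ROI '%s' has %d pixels, outside the expected 480-700 range",
                      rois$labels[i], n))
    block <- cube$data[li, pi, , drop = FALSE]
    Xs[[i]] <- matrix(block, n, d[3])
    ys[[i]] <- rep(rois$classes[i], n)
    grid <- expand.grid(line = li - 1L, pixel = pi - 1L)
    prov[[i]] <- data.frame(roi = rois$labels[i], line = grid$line,
                            pixel = grid$pixel)
  }
  structure(list(X = do.call(rbind, Xs), y = unlist(ys),
                 provenance = do.call(rbind, prov), axis = cube$axis),
            class = "labeled_spectra")
}

#' Sample labeled spectra from ground-truth masks
#'
#' For synthetic scenes the truth masks are the natural ROIs: this samples up
#' to `n_per_class` pixel spectra per class (upper, bottom, skin) from the
#' scene's truth masks, deterministically under `seed`.
#'
#' @param scene an `mfi_scene` from [render_scene()].
#' @param n_per_class pixels to draw per class.
#' @param seed sampling seed.
#' @return A `labeled_spectra` list (see [extract_roi_spectra()]).
#' @export
labeled_spectra_from_truth <- function(scene, n_per_class = 600L, seed = 1L) {
  X <- cube_to_matrix(scene$cube)
  nl <- dim(scene$cube$data)[1]
  idx_class <- list(
    upper  = unlist(lapply(scene$truth$spots,
                           function(s) if (s$class == "upper") which(s$mask))),
    bottom = unlist(lapply(scene$truth$spots,
                           function(s) if (s$class == "bottom") which(s$mask))),
    skin   = which(scene$truth$skin_only_mask))
  old <- .Random.seed_exists()
  set.seed(seed)
  rows <- list(); ys <- list(); prov <- list()
  for (cls in names(idx_class)) {
    idx <- idx_class[[cls]]
    if (length(idx) > n_per_class) idx <- sort(sample(idx, n_per_class))
    rows[[cls]] <- X[idx, , drop = FALSE]
    ys[[cls]] <- rep(cls, length(idx))
    prov[[cls]] <- data.frame(roi = cls, line = (idx - 1L) %% nl,
                              pixel = (idx - 1L) %/% nl)
  }
  .Random.seed_restore(old)
  structure(list(X = do.call(rbind, rows), y = unlist(ys, use.names = FALSE),
                 provenance = do.call(rbind, prov), axis = scene$cube$axis),
            class = "labeled_spectra")
}

#' @export
print.labeled_spectra <- function(x, ...) {
  cat(sprintf("Labeled spectra: %d pixels x %d bands\n", nrow(x$X), ncol(x$X)))
  print(table(x$y))
  invisible(x)
}

#' Write a binary mask as a PNG file
#'
#' @param mask logical matrix.
#' @param path output PNG path (written as 0/255 grayscale).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG written by [write_mask_png()].
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Write labeled spectra as a CSV table
#'
#' Columns: cube_id, line, pixel, label, then one column per band named
#' `b<center nm>`.
#'
#' @param spectra a `labeled_spectra`.
#' @param path CSV output path.
#' @param cube_id identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path, cube_id = "cube") {
  bands <- paste0("b", round(spectra$axis))
  df <- data.frame(cube_id = cube_id,
                   line = spectra$provenance$line,
                   pixel = spectra$provenance$pixel,
                   label = spectra$y)
  df[bands] <- as.data.frame(spectra$X)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
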