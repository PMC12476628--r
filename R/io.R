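#' @include AllClasses.R
NULL

#' Read a heart-beating video from disk
#'
#' Accepts a multi-page TIFF stack or a directory of PNG frames (sorted by
#' file name).  Intensities are returned as read (TIFF/PNG values in
#' [0, 1]); the absolute scale is irrelevant downstream because
#' thresholding is automatic.
#'
#' @param path path to a `.tif`/`.tiff` file or a directory of `.png`
#'   frames.
#' @param fps frames per second of the recording.
#' @param pixelSizeUm optional micrometres-per-pixel calibration.
#' @return A [HeartVideo-class].
#' @export
readHeartVideo <- function(path, fps, pixelSizeUm = NA_real_) {
  if (!file.exists(path))
    cqStop("InputError", sprintf("no such file or directory: %s", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files))
      cqStop("InputError", sprintf("no PNG frames in %s", path))
    pages <- lapply(files, png::readPNG)
  } else {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
      cqStop("InputError", sprintf("unsupported video format: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop colour channels
    p
  })
  fr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  new("HeartVideo", frames = fr, fps = fps, pixelSizeUm = pixelSizeUm,
      params = NULL, groundTruth = data.frame(), seed = NA_integer_)
}

#' Write a heart-beating video to disk
#'
#' Multi-page 16-bit grayscale TIFF (default) or a directory of numbered
#' 16-bit PNG frames.  Intensities are scaled by the video's maximum into
#' [0, 1] before quantization.
#'
#' @param video a [HeartVideo-class].
#' @param path output `.tif` path, or directory path for `format = "png"`.
#' @param format `"tiff"` or `"png"`.
#' @return Invisibly, `path`.
#' @export
writeHeartVideo <- function(video, path, format = c("tiff", "png")) {
  stopifnot(is(video, "HeartVideo"))
  format <- match.arg(format)
  mx <- max(video@frames, 1e-12)
  pages <- lapply(seq_len(nFrames(video)), function(k) {
    p <- pmin(pmax(video@frames[, , k] / mx, 0), 1)
    round(p * 65535) / 65535
  })
  if (format == "tiff") {
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(pages))
      png::writePNG(pages[[k]],
                    file.path(path, sprintf("frame_%05d.png", k)))
  }
  invisible(path)
}

# stable float formatting for byte-identical reruns
writeResultJSON <- function(x, path, digits = 6) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(digits),
                       pretty = TRUE)
  invisible(path)
}

writeTableCSV <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Serialize cardiac metrics for export
#'
#' @param metrics a [CardiacMetrics-class].
#' @return A plain list suitable for JSON export.
#' @export
metricsAsList <- function(metrics) {
  stopifnot(is(metrics, "CardiacMetrics"))
  list(FAC_pct = metrics@fac, FS_pct = metrics@fs,
       ED_Vol = metrics@edVol, ES_Vol = metrics@esVol,
       SV = metrics@sv, CO_per_min = metrics@co, BPM = metrics@bpm,
       n_cycles = metrics@nCycles, axis_convention = metrics@axisConvention,
       flags = metrics@flags)
}

#' Serialize a synergy result for export
#'
#' @param result a [SynergyResult-class].
#' @return A plain list (the additive threshold is included so the
#'   dashed-line reference of combination plots can be drawn).
#' @export
synergyAsList <- function(result) {
  stopifnot(is(result, "SynergyResult"))
  list(metric = result@metricName, E_A = result@eA, E_B = result@eB,
       E_AB = result@eAB, E_additive = result@eAdd, CI = result@ci,
       t = result@statistic, p_value = result@pValue,
       direction = result@direction, n_AB = result@nAB,
       alpha = result@alpha, verdict = result@verdict)
}
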