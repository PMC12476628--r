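#' @include conditions.R geometry.R
NULL

# EBImage::bwlabel is 4-connected; merge labels that touch diagonally so
# components follow 8-connectivity, as expected for blob extraction.
label8 <- function(bw) {
  lab <- EBImage::imageData(EBImage::bwlabel(bw * 1))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  lab
}

#' Segmentation configuration
#'
#' @param sigma Gaussian smoothing sigma in pixels applied before
#'   thresholding (0 disables).
#' @param threshold fixed intensity threshold, or `NULL` for automatic
#'   Otsu thresholding.
#' @param minArea minimum accepted component area in px^2.
#' @param mode `"filled"` — the whole bright region is the chamber — or
#'   `"ring"` — the bright region is the myocardial wall and the chamber
#'   is the cavity enclosed by its inner contour.
#' @param closeSize diameter (px) of the disc brush used for morphological
#'   closing (0 disables).
#' @return A list of validated settings.
#' @export
segmentationConfig <- function(sigma = 1, threshold = NULL, minArea = 20,
                               mode = c("filled", "ring"), closeSize = 5) {
  mode <- match.arg(mode)
  if (sigma < 0 || minArea < 0 || closeSize < 0)
    cqStop("ConfigError", "sigma, minArea and closeSize must be >= 0")
  list(sigma = sigma, threshold = threshold, minArea = minArea,
       mode = mode, closeSize = closeSize)
}

# largest component; ties broken by centroid proximity to the image centre
# (cropped heart videos centre the ventricle)
largestComponent <- function(lab) {
  sizes <- tabulate(lab[lab > 0])
  ids <- which(sizes == max(sizes))
  if (length(ids) > 1L) {
    ctr <- (dim(lab) + 1) / 2
    d2 <- vapply(ids, function(id) {
      px <- which(lab == id, arr.ind = TRUE)
      sum((colMeans(px) - ctr)^2)
    }, numeric(1))
    ids <- ids[which.min(d2)]
  }
  lab == ids[1]
}

#' Segment the ventricular chamber in one frame
#'
#' Pipeline: Gaussian smoothing, intensity thresholding (Otsu by default),
#' morphological closing, hole filling and retention of the largest
#' 8-connected component.  In `"ring"` mode the bright region is taken as
#' the myocardial wall and the returned chamber is the cavity enclosed by
#' the wall's inner contour.
#'
#' @param frame numeric matrix of non-negative intensities (>= 8x8 px).
#' @param cfg a [segmentationConfig()] list.
#' @return Logical matrix of the chamber mask (single connected
#'   component).
#' @section Errors: signals `NoForeground` when nothing survives the
#'   threshold and `TooSmall` when the best component is below
#'   `cfg$minArea`.
#' @examples
#' v <- simulateVideo(heartSimParams(durationS = 1), seed = 1)
#' m <- segmentChamber(frames(v)[, , 1])
#' sum(m) / groundTruth(v)$area[1]  # close to 1
#' @export
segmentChamber <- function(frame, cfg = segmentationConfig()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  if (nrow(frame) < 8L || ncol(frame) < 8L)
    cqStop("ConfigError", "frame must be at least 8x8 pixels")
  sm <- if (cfg$sigma > 0) EBImage::gblur(frame, sigma = cfg$sigma) else frame
  if (is.null(cfg$threshold)) {
    rg <- range(sm)
    if (diff(rg) < .Machine$double.eps)
      cqStop("NoForeground", "frame is constant; no foreground found")
    thr <- rg[1] + diff(rg) *
      EBImage::otsu(EBImage::Image((sm - rg[1]) / diff(rg)))
  } else thr <- cfg$threshold
  bw <- sm > thr
  if (!any(bw))
    cqStop("NoForeground", "no pixel above threshold")
  if (cfg$closeSize >= 3) {
    brush <- EBImage::makeBrush(2 * (cfg$closeSize %/% 2) + 1, shape = "disc")
    bw <- EBImage::imageData(EBImage::closing(bw * 1, brush)) > 0
  }
  if (cfg$mode == "filled") {
    bw <- EBImage::imageData(EBImage::fillHull(bw * 1)) > 0
    mask <- largestComponent(label8(bw))
  } else {
    wall <- largestComponent(label8(bw))
    filled <- EBImage::imageData(EBImage::fillHull(wall * 1)) > 0
    cavity <- filled & !wall
    if (!any(cavity))
      cqStop("NoForeground", "ring mode: wall encloses no cavity")
    mask <- largestComponent(label8(cavity))
  }
  if (sum(mask) < cfg$minArea)
    cqStop("TooSmall", sprintf(
      "largest component (%d px^2) below minArea (%g px^2)",
      sum(mask), cfg$minArea))
  mask
}

#' Measure a chamber mask
#'
#' Area is the pixel count (scaled by `pixelSize^2` when a calibration is
#' supplied), axes come from [minAreaRectangle()], and the centroid is the
#' mean pixel coordinate (row, col).
#'
#' @param mask logical chamber mask.
#' @param frameIndex integer recorded in the result.
#' @param pixelSize micrometres per pixel, or `NA` for pixel units.
#' @return One-row data.frame: `frame`, `area_px2`, `long_px`, `short_px`,
#'   `orientation_deg`, `centroid_r`, `centroid_c`, plus `area`, `long`,
#'   `short` in calibrated units (equal to the pixel columns when
#'   uncalibrated).
#' @export
measureFrame <- function(mask, frameIndex = NA_integer_,
                         pixelSize = NA_real_) {
  mask <- mask > 0
  rect <- minAreaRectangle(mask)
  px <- which(mask, arr.ind = TRUE)
  ps <- if (is.na(pixelSize)) 1 else pixelSize
  data.frame(frame = frameIndex,
             area_px2 = nrow(px),
             long_px = rect[["long"]], short_px = rect[["short"]],
             orientation_deg = rect[["orientation"]],
             centroid_r = mean(px[, 1]), centroid_c = mean(px[, 2]),
             area = nrow(px) * ps^2,
             long = rect[["long"]] * ps, short = rect[["short"]] * ps)
}

#' Segment and measure every frame of a video
#'
#' @param video a [HeartVideo-class].
#' @param cfg a [segmentationConfig()]; when `NULL`, the render mode is
#'   taken from the video's simulation parameters if present.
#' @return data.frame with one [measureFrame()] row per frame.
#' @section Errors: segmentation failures are re-signalled with the frame
#'   index prepended to the message.
#' @export
measureVideo <- function(video, cfg = NULL) {
  stopifnot(is(video, "HeartVideo"))
  if (is.null(cfg)) {
    mode <- if (!is.null(video@params)) video@params@renderMode else "filled"
    cfg <- segmentationConfig(mode = mode)
  }
  nT <- nFrames(video)
  rows <- vector("list", nT)
  for (k in seq_len(nT)) {
    rows[[k]] <- withCallingHandlers(
      tryCatch(
        measureFrame(segmentChamber(video@frames[, , k], cfg),
                     frameIndex = k, pixelSize = video@pixelSizeUm),
        cardioquantError = function(e) {
          cqStop(class(e)[1], sprintf("frame %d: %s", k, conditionMessage(e)))
        }),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  do.call(rbind, rows)
}
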