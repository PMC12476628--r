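#' @include conditions.R
NULL

# boundary pixels of a logical mask: foreground with a background 4-neighbour
# or on the image border
boundaryPixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
        pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(core & !nb, arr.ind = TRUE)
}

#' Minimum-area enclosing rectangle of a chamber mask
#'
#' Fits the rotated rectangle of minimal area around the mask's pixel
#' footprint (the corner points of all boundary pixels, i.e. pixel centres
#' expanded by half a pixel).  The optimum is found by rotating calipers
#' over the convex hull: the minimal rectangle has a side collinear with a
#' hull edge, so only hull-edge directions need to be examined, which makes
#' the result exact.
#'
#' @param mask logical matrix, the chamber mask.
#' @return Named numeric vector `c(long, short, orientation)`: full side
#'   lengths in pixels with `long >= short`, and the orientation of the
#'   long side in degrees in [0, 180), measured counter-clockwise from the
#'   column axis.
#' @examples
#' m <- matrix(FALSE, 30, 40); m[10:19, 10:29] <- TRUE
#' minAreaRectangle(m)  # 20 x 10, orientation 0
#' @export
minAreaRectangle <- function(mask) {
  mask <- mask > 0
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) < 3L)
    cqStop("DegenerateShape", "mask has fewer than 3 pixels")
  # collinear pixel centres carry no 2-d extent worth an axis measurement
  pr <- px[, 1] - px[1, 1]; pc <- px[, 2] - px[1, 2]
  ref <- which(pr != 0 | pc != 0)[1]
  if (is.na(ref) || all(abs(pr * pc[ref] - pc * pr[ref]) < 1e-9))
    cqStop("DegenerateShape", "mask pixels are collinear")
  bp <- boundaryPixels(mask)
  # corner cloud in (x = col, y = -row) coordinates
  x <- c(bp[, 2] - 0.5, bp[, 2] + 0.5, bp[, 2] - 0.5, bp[, 2] + 0.5)
  y <- -c(bp[, 1] - 0.5, bp[, 1] - 0.5, bp[, 1] + 0.5, bp[, 1] + 0.5)
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  best <- list(area = Inf)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    cth <- ex / len; sth <- ey / len
    u <- hx * cth + hy * sth    # along edge
    v <- -hx * sth + hy * cth   # perpendicular
    du <- diff(range(u)); dv <- diff(range(v))
    if (du * dv < best$area)
      best <- list(area = du * dv, du = du, dv = dv,
                   theta = atan2(ey, ex))
  }
  if (!is.finite(best$area))
    cqStop("DegenerateShape", "no valid enclosing rectangle")
  if (best$du >= best$dv) {
    long <- best$du; short <- best$dv; ang <- best$theta
  } else {
    long <- best$dv; short <- best$du; ang <- best$theta + pi / 2
  }
  orientation <- (ang * 180 / pi) %% 180
  c(long = long, short = short, orientation = orientation)
}

# brute-force oracle used in tests and the geometry acceptance check:
# exhaustive sweep of candidate angles (degrees) over the same corner cloud
sweepRectangle <- function(mask, stepDeg = 0.05) {
  mask <- mask > 0
  bp <- boundaryPixels(mask)
  x <- c(bp[, 2] - 0.5, bp[, 2] + 0.5, bp[, 2] - 0.5, bp[, 2] + 0.5)
  y <- -c(bp[, 1] - 0.5, bp[, 1] - 0.5, bp[, 1] + 0.5, bp[, 1] + 0.5)
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  angles <- seq(0, 90 - stepDeg, by = stepDeg) * pi / 180
  best <- c(area = Inf, long = NA, short = NA)
  for (th in angles) {
    u <- hx * cos(th) + hy * sin(th)
    v <- -hx * sin(th) + hy * cos(th)
    du <- diff(range(u)); dv <- diff(range(v))
    if (du * dv < best[["area"]])
      best <- c(area = du * dv, long = max(du, dv), short = min(du, dv))
  }
  best
}
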