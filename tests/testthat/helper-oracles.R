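# Independent geometric oracles used across the test files.  These are
# deliberately naive (pixel-centre rasterization, exhaustive angle sweeps)
# so they share no code with the implementation under test.

# rasterize an ellipse by pixel-centre membership; returns a logical matrix
oracleEllipseMask <- function(nr, nc, center, a, b, thetaDeg = 0) {
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  x <- C - center[2]
  y <- center[1] - R
  th <- thetaDeg * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# rasterize a convex polygon given vertices in (row, col); inside test by
# consistent sign of edge cross products
oracleConvexMask <- function(nr, nc, vr, vc) {
  h <- grDevices::chull(vc, -vr)
  vr <- vr[h]; vc <- vc[h]
  k <- length(vr)
  # orient the hull counter-clockwise in (x = col, y = -row)
  jj <- c(2:k, 1L)
  signedArea <- sum(vc * (-vr[jj]) - vc[jj] * (-vr)) / 2
  if (signedArea < 0) { vr <- rev(vr); vc <- rev(vc) }
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- matrix(TRUE, nr, nc)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    ex <- vc[j] - vc[i]; ey <- -(vr[j] - vr[i])
    qx <- C - vc[i]; qy <- -(R - vr[i])
    inside <- inside & (ex * qy - ey * qx >= 0)
  }
  inside
}

# a random convex blob mask inside an nr x nc frame
randomConvexMask <- function(nr = 80, nc = 80, npts = 10) {
  vr <- runif(npts, nr * 0.25, nr * 0.75)
  vc <- runif(npts, nc * 0.25, nc * 0.75)
  oracleConvexMask(nr, nc, vr, vc)
}

# exhaustive minimum-area-rectangle sweep over all mask pixel corners
# (independent of the package's hull-based search)
oracleSweepRect <- function(mask, stepDeg = 0.05) {
  px <- which(mask, arr.ind = TRUE)
  x <- c(px[, 2] - 0.5, px[, 2] + 0.5, px[, 2] - 0.5, px[, 2] + 0.5)
  y <- -c(px[, 1] - 0.5, px[, 1] - 0.5, px[, 1] + 0.5, px[, 1] + 0.5)
  h <- grDevices::chull(x, y)   # extreme points only; bounding box unchanged
  x <- x[h]; y <- y[h]
  angles <- seq(0, 90 - stepDeg, by = stepDeg) * pi / 180
  best <- c(area = Inf, long = NA_real_, short = NA_real_)
  for (th in angles) {
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    du <- diff(range(u)); dv <- diff(range(v))
    if (du * dv < best[["area"]])
      best <- c(area = du * dv, long = max(du, dv), short = min(du, dv))
  }
  best
}

# default simulation parameters used in several files: 2 s at 100 fps,
# 120 BPM, true FAC 40%
defaultParams <- function(...) heartSimParams(...)

# noise sd giving signal-to-noise ratio ~5 for the default render levels
snr5Sd <- function(params = defaultParams()) {
  (params@signalLevel) / 5
}
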