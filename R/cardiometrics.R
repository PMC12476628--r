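#' @include conditions.R segmentation.R
NULL

#' Fractional area change
#'
#' `FAC = (EDA - ESA) / EDA * 100` (percent).  The formula is total: when
#' ESA exceeds EDA (a segmentation failure upstream) the negative value is
#' returned together with a `NegativeMetric` warning rather than clamped,
#' so failures stay diagnosable.
#'
#' @param eda,esa end-diastolic and end-systolic chamber areas
#'   (vectorized).
#' @return FAC in percent.
#' @examples
#' computeFAC(1000, 600)  # 40
#' @export
computeFAC <- function(eda, esa) {
  if (any(eda <= 0))
    cqStop("InvalidMeasurement", "EDA must be positive")
  out <- (eda - esa) / eda * 100
  if (any(out < 0))
    cqWarn("NegativeMetric", "FAC is negative (ESA > EDA)")
  out
}

#' Fractional shortening
#'
#' `FS = (EDa - ESa) / EDa * 100` (percent), from the long axis at
#' end-diastole and end-systole.  Invariant to whether semi- or full axes
#' are supplied, and to uniform rescaling.
#'
#' @param eda,esa end-diastolic and end-systolic long-axis lengths
#'   (vectorized).
#' @return FS in percent.
#' @examples
#' computeFS(10, 8)  # 20
#' @export
computeFS <- function(eda, esa) {
  if (any(eda <= 0))
    cqStop("InvalidMeasurement", "EDa must be positive")
  out <- (eda - esa) / eda * 100
  if (any(out < 0))
    cqWarn("NegativeMetric", "FS is negative (ESa > EDa)")
  out
}

#' Ellipsoid volumes, stroke volume and cardiac output
#'
#' Prolate-spheroid model: `Vol = 4 pi / 3 * (a * b^2)` evaluated at ED and
#' ES with the axes exactly as supplied, `SV = ED.Vol - ES.Vol` and
#' `CO = SV * BPM`.  Passing full side lengths instead of semi-axes scales
#' every volume by exactly 8 (`(2a)(2b)^2 = 8 a b^2`).
#'
#' @param edA,edB,esA,esB long and short axes at ED and ES.
#' @param bpm heart rate in beats per minute.
#' @return Named numeric `c(ed_vol, es_vol, sv, co)`.
#' @examples
#' computeVolumes(10, 6, 8, 5, bpm = 120)
#' @export
computeVolumes <- function(edA, edB, esA, esB, bpm) {
  stopifnot(bpm > 0)
  edVol <- 4 * pi / 3 * (edA * edB^2)
  esVol <- 4 * pi / 3 * (esA * esB^2)
  svol <- edVol - esVol
  c(ed_vol = edVol, es_vol = esVol, sv = svol, co = svol * bpm)
}

#' Build an area trace from per-frame measurements
#'
#' Orders measurements by frame index and attaches a moving-average
#' smoothed copy used only for cycle detection; per-cycle areas and axes
#' are always read from the raw measurements.
#'
#' @param measurements data.frame from [measureVideo()] (needs columns
#'   `frame`, `area`, `long`, `short`).
#' @param fps frames per second.
#' @param smoothWindow moving-average window in frames (odd; 1 disables).
#' @return A list of class `"AreaTrace"`: `times`, `areas`, `smoothed`,
#'   `fps`, `measurements`.
#' @section Errors: signals `GapInTrace` when frame indices are not
#'   contiguous.
#' @export
buildTrace <- function(measurements, fps, smoothWindow = 3) {
  stopifnot(is.data.frame(measurements), fps > 0)
  m <- measurements[order(measurements$frame), , drop = FALSE]
  if (nrow(m) < 8L)
    cqStop("GapInTrace", "need at least 8 frames")
  if (!identical(as.integer(m$frame), seq(min(m$frame), max(m$frame))))
    cqStop("GapInTrace", "frame indices must be contiguous")
  areas <- m$area
  sm <- if (smoothWindow > 1) movingAverage(areas, smoothWindow) else areas
  structure(list(times = (m$frame - min(m$frame)) / fps, areas = areas,
                 smoothed = sm, fps = fps, measurements = m),
            class = "AreaTrace")
}

# centred moving average with shrinking windows at the ends
movingAverage <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

# alternating extrema of a 1-d series by run-length compression plus
# persistence pruning: repeatedly drop the adjacent extremum pair with the
# smallest amplitude difference until all pairs differ by >= minProm.
findExtrema <- function(x, minProm) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 2L) return(data.frame(index = integer(), type = integer()))
  ends <- cumsum(r$lengths)
  mids <- ends - (r$lengths - 1L) %/% 2L
  v <- r$values
  type <- integer(k)
  for (i in seq_len(k)) {
    lo <- if (i > 1) v[i - 1] else -Inf
    hi <- if (i < k) v[i + 1] else -Inf
    if (v[i] > max(lo, hi)) type[i] <- 1L
    lo <- if (i > 1) v[i - 1] else Inf
    hi <- if (i < k) v[i + 1] else Inf
    if (v[i] < min(lo, hi)) type[i] <- -1L
  }
  # boundary runs are candidate extrema of whichever direction they face
  if (type[1] == 0L) type[1] <- if (v[1] > v[2]) 1L else -1L
  if (type[k] == 0L) type[k] <- if (v[k] > v[k - 1]) 1L else -1L
  sel <- which(type != 0L)
  ev <- v[sel]; eidx <- mids[sel]; etype <- type[sel]
  while (length(ev) >= 2L) {
    d <- abs(diff(ev))
    if (min(d) >= minProm) break
    j <- which.min(d)
    keep <- setdiff(seq_along(ev), c(j, j + 1L))
    ev <- ev[keep]; eidx <- eidx[keep]; etype <- etype[keep]
  }
  data.frame(index = eidx, type = etype)
}

#' Detect cardiac cycles on an area trace
#'
#' End-diastole (ED) frames are local maxima and end-systole (ES) frames
#' local minima of the smoothed trace, retained when their amplitude
#' relative to neighbouring extrema is at least `minProminence` of the
#' trace amplitude.  Each cycle pairs one ED with the following ES; areas
#' and axes are read from the unsmoothed measurements at those frames,
#' with the axis convention applied (`"semi"` halves the rectangle side
#' lengths).
#'
#' @param trace an `"AreaTrace"` from [buildTrace()].
#' @param minProminence relative prominence threshold in (0, 1).
#' @param minCycles minimum number of complete cycles required.
#' @param convention `"semi"` or `"literal"` axis convention.
#' @return data.frame with one row per cycle: `ed_frame`, `es_frame`,
#'   `EDA`, `ESA`, `EDa`, `EDb`, `ESa`, `ESb`.
#' @section Errors: signals `InsufficientCycles` when fewer than
#'   `minCycles` complete cycles are found.
#' @export
detectCycles <- function(trace, minProminence = 0.1, minCycles = 4,
                         convention = c("semi", "literal")) {
  stopifnot(inherits(trace, "AreaTrace"))
  convention <- match.arg(convention)
  amp <- diff(range(trace$smoothed))
  ext <- if (amp > 0)
    findExtrema(trace$smoothed, minProm = minProminence * amp)
  else data.frame(index = integer(), type = integer())
  eds <- ext$index[ext$type == 1L]
  cycles <- list()
  for (e in eds) {
    nxt <- ext$index[ext$type == -1L & ext$index > e]
    if (!length(nxt)) next
    cycles[[length(cycles) + 1L]] <- c(ed = e, es = min(nxt))
  }
  if (length(cycles) < minCycles)
    cqStop("InsufficientCycles", sprintf(
      "found %d complete cycles, need %d", length(cycles), minCycles))
  m <- trace$measurements
  half <- if (convention == "semi") 0.5 else 1
  rows <- lapply(cycles, function(cy) {
    ed <- cy[["ed"]]; es <- cy[["es"]]
    data.frame(ed_frame = m$frame[ed], es_frame = m$frame[es],
               EDA = m$area[ed], ESA = m$area[es],
               EDa = m$long[ed] * half, EDb = m$short[ed] * half,
               ESa = m$long[es] * half, ESb = m$short[es] * half)
  })
  out <- do.call(rbind, rows)
  attr(out, "ed_frames") <- m$frame[eds]
  attr(out, "convention") <- convention
  out
}

#' Estimate heart rate from detected cycles
#'
#' Default `"count"`: the number of complete cycles divided by the trace
#' duration, mirroring manual beat counting over a fixed-length video;
#' exact whenever the recording spans an integer number of cycles.  The
#' `"median_interval"` method (`60 / median inter-ED interval` in seconds)
#' is robust to a truncated final cycle but inherits the +/- one frame
#' localization jitter of the ED peaks.
#'
#' @param cycles result of [detectCycles()].
#' @param trace the `"AreaTrace"` the cycles came from.
#' @param method `"count"` or `"median_interval"`.
#' @return Heart rate in beats per minute.
#' @export
estimateBPM <- function(cycles, trace,
                        method = c("count", "median_interval")) {
  method <- match.arg(method)
  eds <- attr(cycles, "ed_frames")
  if (method == "median_interval") {
    if (length(eds) < 2L) {
      # single complete cycle: fall back to ED -> ES -> implied period
      return(nrow(cycles) / (max(trace$times) + 1 / trace$fps) * 60)
    }
    60 / median(diff(eds) / trace$fps)
  } else {
    nrow(cycles) / (max(trace$times) + 1 / trace$fps) * 60
  }
}

#' Quantify cardiac function from a heart-beating video
#'
#' End-to-end analysis: every frame is segmented ([segmentChamber()]) and
#' measured ([measureFrame()]), the area trace is assembled and cycles are
#' detected ([detectCycles()]); FAC, FS and stroke volume are computed per
#' cycle and averaged (mean over at least `minCycles` cycles), heart rate
#' comes from [estimateBPM()], and cardiac output is `mean(SV) * BPM`.
#'
#' @param video a [HeartVideo-class].
#' @param cfg a [segmentationConfig()], or `NULL` to infer the render mode
#'   from simulation parameters.
#' @param smoothWindow,minProminence,minCycles cycle-detection settings,
#'   see [buildTrace()] and [detectCycles()].
#' @param convention axis convention for volumes, `"semi"` (default) or
#'   `"literal"`.
#' @param bpmMethod see [estimateBPM()].
#' @param average `"mean"` (default) or `"median"` across cycles.
#' @return A [CardiacMetrics-class]; its `perCycle` slot holds the
#'   per-cycle table and `flags` any quality warnings.
#' @examples
#' v <- simulateVideo(heartSimParams(), seed = 1)
#' quantifyVideo(v)
#' @export
quantifyVideo <- function(video, cfg = NULL, smoothWindow = 3,
                          minProminence = 0.1, minCycles = 4,
                          convention = c("semi", "literal"),
                          bpmMethod = c("count", "median_interval"),
                          average = c("mean", "median")) {
  stopifnot(is(video, "HeartVideo"))
  convention <- match.arg(convention)
  bpmMethod <- match.arg(bpmMethod)
  average <- match.arg(average)
  agg <- if (average == "mean") mean else median
  meas <- measureVideo(video, cfg)
  trace <- buildTrace(meas, fps = video@fps, smoothWindow = smoothWindow)
  cycles <- detectCycles(trace, minProminence = minProminence,
                         minCycles = minCycles, convention = convention)
  heartRate <- estimateBPM(cycles, trace, method = bpmMethod)
  flags <- character()
  facPC <- withCallingHandlers(
    computeFAC(cycles$EDA, cycles$ESA),
    NegativeMetric = function(w) {
      flags <<- union(flags, "negative_fac"); invokeRestart("muffleWarning")
    })
  fsPC <- withCallingHandlers(
    computeFS(cycles$EDa, cycles$ESa),
    NegativeMetric = function(w) {
      flags <<- union(flags, "negative_fs"); invokeRestart("muffleWarning")
    })
  vols <- mapply(function(ea, eb, sa, sb)
    computeVolumes(ea, eb, sa, sb, bpm = heartRate),
    cycles$EDa, cycles$EDb, cycles$ESa, cycles$ESb)
  perCycle <- cbind(cycles,
                    FAC = facPC, FS = fsPC,
                    ed_vol = vols["ed_vol", ], es_vol = vols["es_vol", ],
                    SV = vols["sv", ])
  svMean <- agg(perCycle$SV)
  new("CardiacMetrics",
      fac = agg(facPC), fs = agg(fsPC),
      edVol = agg(perCycle$ed_vol), esVol = agg(perCycle$es_vol),
      sv = svMean, co = svMean * heartRate, bpm = heartRate,
      nCycles = nrow(perCycle), axisConvention = convention,
      perCycle = perCycle, flags = flags)
}
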