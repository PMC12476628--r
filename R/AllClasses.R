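#' @include conditions.R
NULL

# ---------------------------------------------------------------------------
# HeartSimParams
# ---------------------------------------------------------------------------

#' Parameters of the synthetic beating-heart video generator
#'
#' Describes the geometry, kinetics, optics and noise of a simulated
#' fluorescent ventricle.  The chamber is an ellipse whose semi-axes
#' oscillate between end-diastole (`edSemiAxes`) and end-systole
#' (`edSemiAxes * (1 - contractionFrac)`) following an asymmetric
#' raised-cosine waveform at `bpm` beats per minute.
#'
#' @slot imageShape integer(2), frame size as (rows, cols) in pixels.
#' @slot fps numeric(1), frames per second.
#' @slot durationS numeric(1), video duration in seconds.
#' @slot bpm numeric(1), true heart rate in beats per minute.
#' @slot center numeric(2), chamber centre as (row, col) in pixels.
#' @slot orientationDeg numeric(1), long-axis orientation in degrees,
#'   measured counter-clockwise from the column (x) axis.
#' @slot edSemiAxes numeric(2), end-diastolic long and short semi-axes
#'   (a_ed, b_ed) in pixels, with a_ed >= b_ed.
#' @slot contractionFrac numeric(2), fractional shortening (f_a, f_b) of
#'   each semi-axis at end-systole, each in [0, 1).
#' @slot systolicFraction numeric(1), fraction of the cycle spent
#'   contracting, in (0, 1).
#' @slot renderMode character(1), `"filled"` (whole chamber bright) or
#'   `"ring"` (bright myocardial wall around a dark cavity).
#' @slot wallThicknessPx numeric(1), wall thickness in pixels (ring mode).
#' @slot psfSigmaPx numeric(1), Gaussian point-spread-function sigma (px).
#' @slot backgroundLevel,signalLevel numeric(1), background and chamber
#'   intensities in arbitrary units.
#' @slot noiseGaussianSd numeric(1), additive Gaussian read-noise sd.
#' @slot noisePoissonScale numeric(1), photons per intensity unit for shot
#'   noise; 0 disables.
#' @slot jitterPx numeric(1), amplitude of per-frame uniform translation of
#'   the chamber centre (px).
#' @slot distractors list of static bright blobs, each a list with elements
#'   `center` (row, col), `semiAxes` (a, b) and `intensity`.
#'
#' @seealso [heartSimParams()], [simulateVideo()], [analyticMetrics()]
#' @export
setClass("HeartSimParams", representation(
  imageShape = "integer",
  fps = "numeric",
  durationS = "numeric",
  bpm = "numeric",
  center = "numeric",
  orientationDeg = "numeric",
  edSemiAxes = "numeric",
  contractionFrac = "numeric",
  systolicFraction = "numeric",
  renderMode = "character",
  wallThicknessPx = "numeric",
  psfSigmaPx = "numeric",
  backgroundLevel = "numeric",
  signalLevel = "numeric",
  noiseGaussianSd = "numeric",
  noisePoissonScale = "numeric",
  jitterPx = "numeric",
  distractors = "list"
))

setValidity("HeartSimParams", function(object) {
  p <- object
  msg <- character()
  if (length(p@imageShape) != 2L || any(p@imageShape < 8L))
    msg <- c(msg, "imageShape must be two integers >= 8")
  if (p@fps <= 0 || p@durationS <= 0)
    msg <- c(msg, "fps and durationS must be positive")
  if (p@fps * p@durationS < 8)
    msg <- c(msg, "video must contain at least 8 frames")
  if (p@bpm <= 0 || p@bpm * p@durationS / 60 < 1)
    msg <- c(msg, "video must span at least one full cardiac cycle")
  a <- p@edSemiAxes
  if (length(a) != 2L || a[2] <= 0 || a[1] < a[2])
    msg <- c(msg, "edSemiAxes must satisfy a_ed >= b_ed > 0")
  f <- p@contractionFrac
  if (length(f) != 2L || any(f < 0) || any(f >= 1))
    msg <- c(msg, "contractionFrac values must lie in [0, 1)")
  if (p@systolicFraction <= 0 || p@systolicFraction >= 1)
    msg <- c(msg, "systolicFraction must lie in (0, 1)")
  if (!p@renderMode %in% c("filled", "ring"))
    msg <- c(msg, "renderMode must be 'filled' or 'ring'")
  if (p@renderMode == "ring" && p@wallThicknessPx <= 0)
    msg <- c(msg, "wallThicknessPx must be positive in ring mode")
  if (any(c(p@psfSigmaPx, p@backgroundLevel, p@noiseGaussianSd,
            p@noisePoissonScale, p@jitterPx) < 0))
    msg <- c(msg, "psfSigmaPx, backgroundLevel, noise and jitter must be >= 0")
  # outermost extent of the chamber (plus wall and jitter) must fit in frame
  reach <- a[1] + ifelse(p@renderMode == "ring", p@wallThicknessPx, 0) +
    p@jitterPx
  if (length(p@center) == 2L) {
    if (p@center[1] - reach < 1 || p@center[1] + reach > p@imageShape[1] ||
        p@center[2] - reach < 1 || p@center[2] + reach > p@imageShape[2])
      msg <- c(msg, "chamber geometry exceeds image bounds")
  } else msg <- c(msg, "center must have length 2")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct simulation parameters for a synthetic beating-heart video
#'
#' Defaults describe a 128x128 px, 2 s, 100 fps recording of a ventricle
#' beating at 120 BPM with end-diastolic semi-axes (30, 18) px and a
#' contraction amplitude chosen so the true fractional area change is 40%.
#'
#' @param imageShape,fps,durationS,bpm,center,orientationDeg,edSemiAxes
#'   see [HeartSimParams-class].
#' @param contractionFrac,systolicFraction,renderMode,wallThicknessPx
#'   see [HeartSimParams-class].
#' @param psfSigmaPx,backgroundLevel,signalLevel,noiseGaussianSd
#'   see [HeartSimParams-class].
#' @param noisePoissonScale,jitterPx,distractors see [HeartSimParams-class].
#' @return A validated [HeartSimParams-class] object.
#' @examples
#' p <- heartSimParams()
#' analyticMetrics(p)
#' @export
heartSimParams <- function(imageShape = c(128L, 128L),
                           fps = 100,
                           durationS = 2,
                           bpm = 120,
                           center = (imageShape + 1) / 2,
                           orientationDeg = 0,
                           edSemiAxes = c(30, 18),
                           contractionFrac = rep(1 - sqrt(0.6), 2),
                           systolicFraction = 0.4,
                           renderMode = c("filled", "ring"),
                           wallThicknessPx = 4,
                           psfSigmaPx = 1,
                           backgroundLevel = 0.1,
                           signalLevel = 1,
                           noiseGaussianSd = 0,
                           noisePoissonScale = 0,
                           jitterPx = 0,
                           distractors = list()) {
  renderMode <- match.arg(renderMode)
  obj <- try(new("HeartSimParams",
    imageShape = as.integer(imageShape), fps = fps, durationS = durationS,
    bpm = bpm, center = as.numeric(center),
    orientationDeg = orientationDeg, edSemiAxes = as.numeric(edSemiAxes),
    contractionFrac = as.numeric(contractionFrac),
    systolicFraction = systolicFraction, renderMode = renderMode,
    wallThicknessPx = wallThicknessPx, psfSigmaPx = psfSigmaPx,
    backgroundLevel = backgroundLevel, signalLevel = signalLevel,
    noiseGaussianSd = noiseGaussianSd,
    noisePoissonScale = noisePoissonScale, jitterPx = jitterPx,
    distractors = distractors), silent = TRUE)
  if (inherits(obj, "try-error"))
    cqStop("ConfigError", attr(obj, "condition")$message)
  obj
}

# ---------------------------------------------------------------------------
# HeartVideo
# ---------------------------------------------------------------------------

#' A heart-beating video with optional simulation ground truth
#'
#' Container for a grayscale fluorescence time-lapse of a beating heart.
#' Videos loaded from disk carry only frames, frame rate and pixel size;
#' simulated videos additionally carry the generating parameters, the seed
#' and a per-frame ground-truth table (true semi-axes and chamber area).
#'
#' @slot frames numeric array (rows x cols x frames), non-negative
#'   intensities.
#' @slot fps numeric(1), frames per second.
#' @slot pixelSizeUm numeric(1), micrometres per pixel, or `NA` if
#'   uncalibrated.
#' @slot params the generating [HeartSimParams-class], or `NULL` for loaded
#'   videos.
#' @slot groundTruth data.frame with columns `frame`, `time_s`, `a`, `b`,
#'   `area` (true semi-axes in px and analytic chamber area in px^2);
#'   empty for loaded videos.
#' @slot seed integer(1), simulation seed (`NA` for loaded videos).
#'
#' @seealso [simulateVideo()], [readHeartVideo()], [quantifyVideo()]
#' @export
setClass("HeartVideo", representation(
  frames = "array",
  fps = "numeric",
  pixelSizeUm = "numeric",
  params = "ANY",
  groundTruth = "data.frame",
  seed = "integer"
))

setValidity("HeartVideo", function(object) {
  d <- dim(object@frames)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "frames must be a 3-d array")
  else {
    if (d[1] < 8L || d[2] < 8L) msg <- c(msg, "frames must be at least 8x8")
    if (!all(is.finite(object@frames))) msg <- c(msg, "frame intensities must be finite")
  }
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (nrow(object@groundTruth) > 0 && nrow(object@groundTruth) != d[3])
    msg <- c(msg, "groundTruth must have one row per frame")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

# ---------------------------------------------------------------------------
# CardiacMetrics
# ---------------------------------------------------------------------------

#' Cycle-averaged cardiac function metrics
#'
#' Result container of [quantifyVideo()] and [analyticMetrics()].  Units:
#' FAC and FS in percent; volumes in px^3 (or um^3 when a pixel size is
#' supplied); cardiac output in volume per minute; heart rate in beats per
#' minute.
#'
#' @slot fac,fs numeric(1), fractional area change and fractional
#'   shortening in percent.
#' @slot edVol,esVol,sv numeric(1), end-diastolic volume, end-systolic
#'   volume and stroke volume.
#' @slot co numeric(1), cardiac output = SV x BPM.
#' @slot bpm numeric(1), heart rate.
#' @slot nCycles integer(1), number of complete cycles averaged.
#' @slot axisConvention character(1), `"semi"` (rectangle side / 2 fed to
#'   the prolate-spheroid volume formula) or `"literal"` (full side
#'   lengths fed to the formula unchanged).
#' @slot perCycle data.frame of per-cycle quantities (ED/ES frames, areas,
#'   axes, FAC, FS, SV); empty for analytic metrics.
#' @slot flags character vector of quality warnings (e.g.
#'   `"negative_fac"`), empty when clean.
#'
#' @seealso [fac()], [fs()], [sv()], [co()], [bpm()]
#' @export
setClass("CardiacMetrics", representation(
  fac = "numeric", fs = "numeric",
  edVol = "numeric", esVol = "numeric", sv = "numeric", co = "numeric",
  bpm = "numeric", nCycles = "integer", axisConvention = "character",
  perCycle = "data.frame", flags = "character"
))

setValidity("CardiacMetrics", function(object) {
  msg <- character()
  if (!object@axisConvention %in% c("semi", "literal"))
    msg <- c(msg, "axisConvention must be 'semi' or 'literal'")
  if (length(object@fac) != 1L || length(object@bpm) != 1L)
    msg <- c(msg, "metrics must be scalars")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

# ---------------------------------------------------------------------------
# CohortDesign
# ---------------------------------------------------------------------------

#' Design of a simulated treatment cohort for synergy analysis
#'
#' Group means are derived from chosen true rescue effects by inverting the
#' normalization used downstream, so effect recovery is well-posed: with
#' zero animal-level noise the synergy module recovers the design exactly.
#'
#' @slot metricName character(1), endpoint label.
#' @slot control,model named numeric(3) `(n, mean, sd)` for the healthy
#'   control and disease model groups (raw metric units).
#' @slot treatments data.frame with columns `name`, `n`, `trueE`, `sd`:
#'   the single-agent groups and their true rescue effects in [0, 1].
#' @slot combination named numeric(3) `(n, gamma, sd)`; the combination
#'   group's true effect is `min(1, gamma * E_add)` where `E_add` is the
#'   Bliss additive threshold of the first two treatments, so `gamma > 1`
#'   builds in synergy, `gamma = 1` exact additivity.
#' @slot orientation character(1), `"higher_better"` or `"lower_better"`.
#' @slot normalizationMode character(1), `"ratio_to_control"` or
#'   `"baseline_corrected"` (see [normalizeRescue()]).
#'
#' @seealso [cohortDesign()], [simulateCohort()], [analyzeSynergy()]
#' @export
setClass("CohortDesign", representation(
  metricName = "character",
  control = "numeric", model = "numeric",
  treatments = "data.frame",
  combination = "numeric",
  orientation = "character",
  normalizationMode = "character"
))

setValidity("CohortDesign", function(object) {
  msg <- character()
  ok3 <- function(x, nm) length(x) == 3L && all(nm %in% names(x))
  if (!ok3(object@control, c("n", "mean", "sd")) ||
      !ok3(object@model, c("n", "mean", "sd")))
    msg <- c(msg, "control and model must be named (n, mean, sd)")
  if (!ok3(object@combination, c("n", "gamma", "sd")))
    msg <- c(msg, "combination must be named (n, gamma, sd)")
  else if (object@combination[["gamma"]] <= 0)
    msg <- c(msg, "synergy factor gamma must be positive")
  tr <- object@treatments
  if (!all(c("name", "n", "trueE", "sd") %in% names(tr)) || nrow(tr) < 2L)
    msg <- c(msg, "treatments needs columns name, n, trueE, sd and >= 2 rows")
  else {
    if (any(tr$trueE < 0 | tr$trueE > 1))
      msg <- c(msg, "trueE must lie in [0, 1]")
    if (any(tr$sd < 0) || any(tr$n < 2))
      msg <- c(msg, "treatment n >= 2 and sd >= 0 required")
  }
  ns <- c(object@control[["n"]], object@model[["n"]], object@combination[["n"]])
  if (any(ns < 2)) msg <- c(msg, "all group sizes must be >= 2")
  if (any(c(object@control[["sd"]], object@model[["sd"]],
            object@combination[["sd"]]) < 0))
    msg <- c(msg, "all sd must be >= 0")
  if (!object@orientation %in% c("higher_better", "lower_better"))
    msg <- c(msg, "orientation must be 'higher_better' or 'lower_better'")
  if (!object@normalizationMode %in% c("ratio_to_control", "baseline_corrected"))
    msg <- c(msg, "unknown normalizationMode")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a cohort design
#'
#' Defaults mirror a typical rescue experiment: control and disease-model
#' groups of 10 animals, two single agents with true rescue effects 0.6 and
#' 0.5, and a combination group whose true effect exceeds the Bliss
#' additive threshold by the factor `gamma`.
#'
#' @param metricName endpoint label.
#' @param control,model numeric `(n, mean, sd)` in raw metric units.
#' @param treatments data.frame(name, n, trueE, sd).
#' @param combination numeric `(n, gamma, sd)`.
#' @param orientation,normalizationMode see [CohortDesign-class].
#' @return A validated [CohortDesign-class].
#' @examples
#' d <- cohortDesign()
#' sim <- simulateCohort(d, seed = 1)
#' head(sim$table)
#' @export
cohortDesign <- function(metricName = "FAC",
                         control = c(n = 10, mean = 1, sd = 0.05),
                         model = c(n = 10, mean = 0.2, sd = 0.05),
                         treatments = data.frame(
                           name = c("A", "B"), n = 10,
                           trueE = c(0.6, 0.5), sd = 0.05),
                         combination = c(n = 10, gamma = 1.125, sd = 0.05),
                         orientation = c("higher_better", "lower_better"),
                         normalizationMode = c("ratio_to_control",
                                               "baseline_corrected")) {
  orientation <- match.arg(orientation)
  normalizationMode <- match.arg(normalizationMode)
  obj <- try(new("CohortDesign", metricName = metricName, control = control,
    model = model, treatments = treatments, combination = combination,
    orientation = orientation, normalizationMode = normalizationMode),
    silent = TRUE)
  if (inherits(obj, "try-error"))
    cqStop("ConfigError", attr(obj, "condition")$message)
  obj
}

# ---------------------------------------------------------------------------
# SurvivalSimParams
# ---------------------------------------------------------------------------

#' Design of a simulated survival experiment
#'
#' Exponential event times with group-specific hazards, observed on a
#' regular inspection grid (status checked every `gridH` hours up to
#' `horizonH`); deaths are detected at the first check after they occur and
#' animals alive at the horizon are right-censored there.
#'
#' @slot groups data.frame with columns `name`, `n`, `hazard` (per hour).
#' @slot horizonH numeric(1), end of observation in hours.
#' @slot gridH numeric(1), inspection interval in hours.
#' @seealso [survivalSimParams()], [simulateSurvival()]
#' @export
setClass("SurvivalSimParams", representation(
  groups = "data.frame", horizonH = "numeric", gridH = "numeric"
))

setValidity("SurvivalSimParams", function(object) {
  msg <- character()
  g <- object@groups
  if (!all(c("name", "n", "hazard") %in% names(g)) || nrow(g) < 1L)
    msg <- c(msg, "groups needs columns name, n, hazard")
  else if (any(g$hazard < 0) || any(g$n < 1))
    msg <- c(msg, "hazards must be >= 0 and n >= 1")
  if (object@gridH <= 0 || object@horizonH <= 0 ||
      abs(object@horizonH / object@gridH -
          round(object@horizonH / object@gridH)) > 1e-9)
    msg <- c(msg, "horizonH must be a positive multiple of gridH")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct survival-simulation parameters
#'
#' Defaults follow the zebrafish toxin-challenge design: status recorded
#' every 0.5 h up to 32 h, an untreated model group with an appreciable
#' hazard and treatment groups with reduced hazards.
#'
#' @param groups data.frame(name, n, hazard per hour).
#' @param horizonH,gridH observation horizon and inspection interval (h).
#' @return A validated [SurvivalSimParams-class].
#' @export
survivalSimParams <- function(groups = data.frame(
                                name = c("model", "treated"),
                                n = 10, hazard = c(log(2) / 8, log(2) / 32)),
                              horizonH = 32, gridH = 0.5) {
  obj <- try(new("SurvivalSimParams", groups = groups, horizonH = horizonH,
                 gridH = gridH), silent = TRUE)
  if (inherits(obj, "try-error"))
    cqStop("ConfigError", attr(obj, "condition")$message)
  obj
}

# ---------------------------------------------------------------------------
# SurvivalCurve
# ---------------------------------------------------------------------------

#' A Kaplan-Meier survival curve
#'
#' Product-limit estimate over the distinct observed times of one group.
#' `survival[i]` is S(t) just after `time[i]`; S(0) = 1 by convention.
#'
#' @slot group character(1), group label.
#' @slot time numeric, distinct observed times (hours).
#' @slot survival numeric, non-increasing estimates in [0, 1].
#' @slot nRisk,nEvent,nCensor numeric, risk-set size, deaths and censorings
#'   at each time.
#' @seealso [kaplanMeier()], [survivalAt()]
#' @export
setClass("SurvivalCurve", representation(
  group = "character", time = "numeric", survival = "numeric",
  nRisk = "numeric", nEvent = "numeric", nCensor = "numeric"
))

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@survival) != n || length(object@nRisk) != n ||
      length(object@nEvent) != n || length(object@nCensor) != n)
    msg <- c(msg, "all slots must have equal length")
  if (n > 0) {
    if (any(diff(object@survival) > 1e-12))
      msg <- c(msg, "survival must be non-increasing")
    if (any(object@survival < -1e-12 | object@survival > 1 + 1e-12))
      msg <- c(msg, "survival must lie in [0, 1]")
    if (is.unsorted(object@time, strictly = TRUE))
      msg <- c(msg, "time must be strictly increasing")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

# ---------------------------------------------------------------------------
# SynergyResult
# ---------------------------------------------------------------------------

#' Result of a Bliss-Independence synergy analysis for one endpoint
#'
#' @slot metricName character(1), endpoint label.
#' @slot eA,eB,eAB numeric(1), group-mean rescue effects of the two single
#'   agents and the combination.
#' @slot eAdd numeric(1), Bliss additive threshold `eA + eB - eA*eB`.
#' @slot ci numeric(1), combination index `eAdd / eAB` (`NA` when the
#'   combination effect is zero); values below 1 indicate synergy.
#' @slot statistic,pValue numeric(1), one-sample t statistic and two-sided
#'   p-value of the combination group's per-animal effects against `eAdd`.
#' @slot direction numeric(1), sign of `mean(E_AB) - eAdd`.
#' @slot nAB integer(1), combination group size.
#' @slot alpha numeric(1), significance level used for the verdict.
#' @slot verdict character(1), one of `"synergy"`, `"additive"`,
#'   `"antagonism"`, `"undefined"`.
#' @slot effects data.frame of per-animal normalized effects (columns
#'   `animal_id`, `group`, `E`, `clipped`).
#' @seealso [analyzeSynergy()], [combinationIndex()]
#' @export
setClass("SynergyResult", representation(
  metricName = "character",
  eA = "numeric", eB = "numeric", eAB = "numeric", eAdd = "numeric",
  ci = "numeric", statistic = "numeric", pValue = "numeric",
  direction = "numeric", nAB = "integer", alpha = "numeric",
  verdict = "character", effects = "data.frame"
))

setValidity("SynergyResult", function(object) {
  msg <- character()
  if (!object@verdict %in% c("synergy", "additive", "antagonism", "undefined"))
    msg <- c(msg, "unknown verdict")
  eAdd <- object@eA + object@eB - object@eA * object@eB
  if (is.finite(object@eAdd) && abs(object@eAdd - eAdd) > 1e-8)
    msg <- c(msg, "eAdd inconsistent with stored group effects")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
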