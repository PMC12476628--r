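#' @include AllClasses.R
NULL

# deterministic per-frame / per-group sub-seed below 2^31
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 2654435) %% 2147483647)
}

#' Contraction waveform of the simulated ventricle
#'
#' Periodic asymmetric raised-cosine: `s = 0` at end-diastole (phase 0),
#' rising to `s = 1` at end-systole after `systolicFraction` of the cycle,
#' then relaxing back to 0.  Semi-axes at time `t` are
#' `edSemiAxes * (1 - contractionFrac * s(t))`.
#'
#' @param t time(s) in seconds (vectorized).
#' @param params a [HeartSimParams-class].
#' @return Numeric vector of contraction levels in [0, 1].
#' @examples
#' p <- heartSimParams()
#' contractionWaveform(c(0, 0.2, 0.5), p)
#' @export
contractionWaveform <- function(t, params) {
  stopifnot(is(params, "HeartSimParams"), all(t >= 0))
  period <- 60 / params@bpm
  u <- (t %% period) / period
  sf <- params@systolicFraction
  ifelse(u <= sf,
         0.5 * (1 - cos(pi * u / sf)),
         0.5 * (1 + cos(pi * (u - sf) / (1 - sf))))
}

# pixel-centre ellipse membership on 1-based (row, col) grids.
# x runs along columns, y upward (negative row direction); theta is the
# CCW angle of the long axis from the x (column) axis.
ellipseInside <- function(R, C, center, a, b, thetaDeg) {
  x <- C - center[2]
  y <- center[1] - R
  th <- thetaDeg * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

renderFrame <- function(params, a, b, dr = 0, dc = 0) {
  nr <- params@imageShape[1]; nc <- params@imageShape[2]
  R <- matrix(seq_len(nr), nr, nc)
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ctr <- params@center + c(dr, dc)
  img <- matrix(params@backgroundLevel, nr, nc)
  if (params@renderMode == "filled") {
    inside <- ellipseInside(R, C, ctr, a, b, params@orientationDeg)
    img[inside] <- img[inside] + params@signalLevel
  } else {
    w <- params@wallThicknessPx
    outer <- ellipseInside(R, C, ctr, a + w, b + w, params@orientationDeg)
    inner <- ellipseInside(R, C, ctr, a, b, params@orientationDeg)
    img[outer & !inner] <- img[outer & !inner] + params@signalLevel
  }
  for (d in params@distractors) {
    ins <- ellipseInside(R, C, d$center, d$semiAxes[1], d$semiAxes[2], 0)
    img[ins] <- img[ins] + d$intensity
  }
  img
}

#' Simulate a fluorescent beating-heart video with ground truth
#'
#' Renders, frame by frame, an elliptical chamber whose semi-axes follow
#' [contractionWaveform()], applies Gaussian point-spread-function blur,
#' then adds Poisson shot noise and Gaussian read noise.  Randomness uses
#' deterministic per-frame sub-streams derived from `seed`, so the same
#' seed always yields bit-identical frames.
#'
#' @param params a [HeartSimParams-class].
#' @param seed integer seed.
#' @param pixelSizeUm optional calibration recorded on the video.
#' @return A [HeartVideo-class] whose `groundTruth` slot holds the true
#'   per-frame semi-axes and analytic chamber area.
#' @examples
#' v <- simulateVideo(heartSimParams(durationS = 1), seed = 1)
#' v
#' @export
simulateVideo <- function(params, seed, pixelSizeUm = NA_real_) {
  stopifnot(is(params, "HeartSimParams"))
  validObject(params)
  nT <- round(params@fps * params@durationS)
  t <- (seq_len(nT) - 1) / params@fps
  s <- contractionWaveform(t, params)
  a <- params@edSemiAxes[1] * (1 - params@contractionFrac[1] * s)
  b <- params@edSemiAxes[2] * (1 - params@contractionFrac[2] * s)
  fr <- array(0, c(params@imageShape[1], params@imageShape[2], nT))
  for (k in seq_len(nT)) {
    withr::with_seed(subSeed(seed, k), {
      dr <- dc <- 0
      if (params@jitterPx > 0) {
        dr <- runif(1, -params@jitterPx, params@jitterPx)
        dc <- runif(1, -params@jitterPx, params@jitterPx)
      }
      img <- renderFrame(params, a[k], b[k], dr, dc)
      if (params@psfSigmaPx > 0)
        img <- EBImage::gblur(img, sigma = params@psfSigmaPx)
      if (params@noisePoissonScale > 0)
        img <- rpois(length(img), pmax(img, 0) * params@noisePoissonScale) /
          params@noisePoissonScale
      if (params@noiseGaussianSd > 0)
        img <- img + rnorm(length(img), 0, params@noiseGaussianSd)
      fr[, , k] <- img
    })
  }
  gt <- data.frame(frame = seq_len(nT), time_s = t, a = a, b = b,
                   area = pi * a * b)
  new("HeartVideo", frames = fr, fps = params@fps,
      pixelSizeUm = pixelSizeUm, params = params, groundTruth = gt,
      seed = as.integer(seed))
}

#' Analytic cardiac metrics implied by simulation parameters
#'
#' Evaluates the cardiac function formulas directly on the generative
#' geometry: `EDA = pi a_ed b_ed`, `ESA = pi a_es b_es`,
#' `FAC = (EDA - ESA)/EDA * 100`, `FS = (a_ed - a_es)/a_ed * 100`,
#' `Vol = 4 pi / 3 (a b^2)` at ED and ES, `SV = ED.Vol - ES.Vol`, and
#' `CO = SV * BPM`.  Under the `"literal"` convention the full axis lengths
#' (twice the semi-axes) are fed to the volume formula unchanged, which
#' scales volumes by exactly 8.
#'
#' @param params a [HeartSimParams-class].
#' @param convention `"semi"` (default) or `"literal"`.
#' @return A [CardiacMetrics-class] with an empty per-cycle table.
#' @examples
#' analyticMetrics(heartSimParams())
#' @export
analyticMetrics <- function(params, convention = c("semi", "literal")) {
  stopifnot(is(params, "HeartSimParams"))
  convention <- match.arg(convention)
  aED <- params@edSemiAxes[1]; bED <- params@edSemiAxes[2]
  aES <- aED * (1 - params@contractionFrac[1])
  bES <- bED * (1 - params@contractionFrac[2])
  EDA <- pi * aED * bED; ESA <- pi * aES * bES
  mult <- if (convention == "semi") 1 else 2
  vols <- computeVolumes(mult * aED, mult * bED, mult * aES, mult * bES,
                         bpm = params@bpm)
  new("CardiacMetrics",
      fac = computeFAC(EDA, ESA), fs = computeFS(aED, aES),
      edVol = vols[["ed_vol"]], esVol = vols[["es_vol"]],
      sv = vols[["sv"]], co = vols[["co"]], bpm = params@bpm,
      nCycles = as.integer(floor(params@bpm * params@durationS / 60)),
      axisConvention = convention,
      perCycle = data.frame(), flags = character())
}

#' Simulate a per-animal treatment cohort with known synergy
#'
#' Draws per-animal endpoint values from Normal(group mean, sd).  Group
#' means for treated groups are obtained by inverting the normalization
#' declared in the design, so the true rescue effects are recovered exactly
#' in the noise-free case.  The combination group's true effect is
#' `min(1, gamma * E_add)`; the true combination index is therefore
#' `E_add / min(1, gamma * E_add)`.
#'
#' @param design a [CohortDesign-class].
#' @param seed integer seed.
#' @return A list with elements `table` (data.frame: `animal_id`, `group`,
#'   `metric`, `value`), `trueCI`, `trueEffects` (named vector including
#'   the combination group `"AB"`), and `design`.
#' @examples
#' sim <- simulateCohort(cohortDesign(), seed = 42)
#' sim$trueCI
#' @export
simulateCohort <- function(design, seed) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  cm <- design@control[["mean"]]; mm <- design@model[["mean"]]
  invertE <- function(E) {
    switch(design@normalizationMode,
      ratio_to_control = {
        if (design@orientation == "higher_better") E * cm
        else {
          if (any(E <= 0))
            cqStop("ConfigError",
                   "lower_better ratio normalization needs trueE > 0")
          cm / E
        }
      },
      baseline_corrected = mm + E * (cm - mm))
  }
  tr <- design@treatments
  eA <- tr$trueE[1]; eB <- tr$trueE[2]
  eAdd <- blissThreshold(eA, eB)
  gamma <- design@combination[["gamma"]]
  eABtrue <- min(1, gamma * eAdd)
  trueCI <- if (eABtrue > 0) eAdd / eABtrue else NA_real_

  specs <- list(
    list(name = "control", n = design@control[["n"]], mean = cm,
         sd = design@control[["sd"]]),
    list(name = "model", n = design@model[["n"]], mean = mm,
         sd = design@model[["sd"]]))
  for (i in seq_len(nrow(tr)))
    specs <- c(specs, list(list(name = tr$name[i], n = tr$n[i],
                                mean = invertE(tr$trueE[i]), sd = tr$sd[i])))
  specs <- c(specs, list(list(name = "AB", n = design@combination[["n"]],
                              mean = invertE(eABtrue),
                              sd = design@combination[["sd"]])))
  rows <- lapply(seq_along(specs), function(i) {
    g <- specs[[i]]
    vals <- withr::with_seed(subSeed(seed, i),
                             rnorm(g$n, mean = g$mean, sd = g$sd))
    data.frame(animal_id = sprintf("%s_%02d", g$name, seq_len(g$n)),
               group = g$name, metric = design@metricName, value = vals)
  })
  trueE <- c(setNames(tr$trueE, tr$name), AB = eABtrue)
  list(table = do.call(rbind, rows), trueCI = trueCI, trueEffects = trueE,
       design = design)
}

#' Simulate an interval-recorded survival experiment
#'
#' Event times are exponential with group-specific hazards; the recorded
#' time is the first inspection-grid point at or after the event (death is
#' detected at the first status check after it occurs).  Animals alive at
#' the horizon are right-censored there.
#'
#' @param params a [SurvivalSimParams-class].
#' @param seed integer seed.
#' @return data.frame with columns `id`, `group`, `time_h`, `event`
#'   (logical; `TRUE` = death observed).
#' @examples
#' head(simulateSurvival(survivalSimParams(), seed = 7))
#' @export
simulateSurvival <- function(params, seed) {
  stopifnot(is(params, "SurvivalSimParams"))
  validObject(params)
  g <- params@groups
  rows <- lapply(seq_len(nrow(g)), function(i) {
    n <- g$n[i]
    raw <- if (g$hazard[i] <= 0) rep(Inf, n)
           else withr::with_seed(subSeed(seed, i), rexp(n, rate = g$hazard[i]))
    grid <- pmax(ceiling(raw / params@gridH) * params@gridH, params@gridH)
    event <- raw <= params@horizonH
    data.frame(id = sprintf("%s_%03d", g$name[i], seq_len(n)),
               group = g$name[i],
               time_h = ifelse(event, grid, params@horizonH),
               event = event)
  })
  do.call(rbind, rows)
}
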