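#' @include AllClasses.R
NULL

#' Accessors for cardioquant objects
#'
#' Small accessor generics returning individual slots of the package's
#' containers: frame data and frame rate of a [HeartVideo-class], the
#' individual metrics of a [CardiacMetrics-class], and the headline numbers
#' of a [SynergyResult-class].
#'
#' @param object a cardioquant object.
#' @return The requested component (a numeric scalar unless noted).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("fac", function(object) standardGeneric("fac"))
#' @rdname accessors
#' @export
setGeneric("fs", function(object) standardGeneric("fs"))
#' @rdname accessors
#' @export
setGeneric("sv", function(object) standardGeneric("sv"))
#' @rdname accessors
#' @export
setGeneric("co", function(object) standardGeneric("co"))
#' @rdname accessors
#' @export
setGeneric("bpm", function(object) standardGeneric("bpm"))
#' @rdname accessors
#' @export
setGeneric("nCycles", function(object) standardGeneric("nCycles"))
#' @rdname accessors
#' @export
setGeneric("perCycle", function(object) standardGeneric("perCycle"))
#' @rdname accessors
#' @export
setGeneric("combinationIndexOf", function(object) standardGeneric("combinationIndexOf"))
#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
setMethod("frames", "HeartVideo", function(object) object@frames)
#' @rdname accessors
setMethod("fps", "HeartVideo", function(object) object@fps)
#' @rdname accessors
setMethod("nFrames", "HeartVideo", function(object) dim(object@frames)[3])
#' @rdname accessors
setMethod("groundTruth", "HeartVideo", function(object) object@groundTruth)

#' @rdname accessors
setMethod("fac", "CardiacMetrics", function(object) object@fac)
#' @rdname accessors
setMethod("fs", "CardiacMetrics", function(object) object@fs)
#' @rdname accessors
setMethod("sv", "CardiacMetrics", function(object) object@sv)
#' @rdname accessors
setMethod("co", "CardiacMetrics", function(object) object@co)
#' @rdname accessors
setMethod("bpm", "CardiacMetrics", function(object) object@bpm)
#' @rdname accessors
setMethod("nCycles", "CardiacMetrics", function(object) object@nCycles)
#' @rdname accessors
setMethod("perCycle", "CardiacMetrics", function(object) object@perCycle)

#' @rdname accessors
setMethod("combinationIndexOf", "SynergyResult", function(object) object@ci)
#' @rdname accessors
setMethod("verdict", "SynergyResult", function(object) object@verdict)
#' @rdname accessors
setMethod("pValue", "SynergyResult", function(object) object@pValue)

setMethod("show", "HeartVideo", function(object) {
  d <- dim(object@frames)
  cat(sprintf("HeartVideo: %d frames of %dx%d px at %g fps (%.2f s)\n",
              d[3], d[1], d[2], object@fps, d[3] / object@fps))
  if (!is.na(object@pixelSizeUm))
    cat(sprintf("  pixel size: %g um/px\n", object@pixelSizeUm))
  if (!is.null(object@params))
    cat(sprintf("  simulated (seed %d): BPM %g, ED semi-axes (%g, %g) px, %s mode\n",
                object@seed, object@params@bpm, object@params@edSemiAxes[1],
                object@params@edSemiAxes[2], object@params@renderMode))
})

setMethod("show", "CardiacMetrics", function(object) {
  cat("CardiacMetrics (axis convention:", object@axisConvention, ")\n")
  cat(sprintf("  FAC %.2f %% | FS %.2f %% | BPM %.1f | cycles %d\n",
              object@fac, object@fs, object@bpm, object@nCycles))
  cat(sprintf("  ED.Vol %.1f | ES.Vol %.1f | SV %.1f | CO %.1f /min\n",
              object@edVol, object@esVol, object@sv, object@co))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "SynergyResult", function(object) {
  cat(sprintf("SynergyResult [%s]\n", object@metricName))
  cat(sprintf("  E_A %.3f  E_B %.3f  E_AB %.3f  E_add %.3f\n",
              object@eA, object@eB, object@eAB, object@eAdd))
  cat(sprintf("  CI %.4f  t %.3f  p %.4g  (n_AB = %d)\n",
              object@ci, object@statistic, object@pValue, object@nAB))
  cat("  verdict:", object@verdict, "\n")
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve [%s]: %d time points, final S = %.3f\n",
              object@group, length(object@time),
              if (length(object@survival)) min(object@survival) else 1))
})

setMethod("show", "HeartSimParams", function(object) {
  cat(sprintf("HeartSimParams: %dx%d px, %g fps, %g s, %g BPM, %s mode\n",
              object@imageShape[1], object@imageShape[2], object@fps,
              object@durationS, object@bpm, object@renderMode))
  cat(sprintf("  ED semi-axes (%g, %g) px, contraction (%.3f, %.3f), FAC_true %.1f %%\n",
              object@edSemiAxes[1], object@edSemiAxes[2],
              object@contractionFrac[1], object@contractionFrac[2],
              (1 - prod(1 - object@contractionFrac)) * 100))
})

#' Plot a Kaplan-Meier curve
#'
#' Draws the survival step function of one [SurvivalCurve-class].
#'
#' @param x a [SurvivalCurve-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
setMethod("plot", signature("SurvivalCurve", "missing"), function(x, y, ...) {
  t <- c(0, x@time)
  s <- c(1, x@survival)
  plot(t, s, type = "s", ylim = c(0, 1), xlab = "time (h)",
       ylab = "survival", main = x@group, ...)
  invisible(x)
})
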