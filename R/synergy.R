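#' @include conditions.R AllClasses.R
NULL

#' Normalize raw endpoints into per-animal rescue effects
#'
#' A rescue effect E expresses how far a treatment restores a disease-model
#' endpoint toward the healthy-control level, nominally in [0, 1] with
#' E = 1 at full restoration.  Two modes are provided:
#'
#' * `ratio_to_control`: `E_i = v_i / mean(control)` for `higher_better`
#'   metrics (the control group is taken as 100% therapeutic effect);
#'   for `lower_better` metrics the ratio is inverted,
#'   `E_i = mean(control) / v_i`, so that values restored down toward
#'   control give E near 1.
#' * `baseline_corrected`:
#'   `E_i = (v_i - mean(model)) / (mean(control) - mean(model))`, which
#'   handles either orientation by construction (the model mean maps to 0,
#'   the control mean to 1).
#'
#' @param table data.frame with columns `animal_id`, `group`, `metric`,
#'   `value`.
#' @param metric endpoint to normalize; `NULL` when the table holds a
#'   single metric.
#' @param mode `"ratio_to_control"` or `"baseline_corrected"`.
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @param clip clip E into [0, 1]? Off by default for transparency; the
#'   `clipped` column flags affected animals either way.
#' @param controlGroup,modelGroup group labels of the healthy control and
#'   the disease model.
#' @return data.frame `animal_id`, `group`, `E`, `clipped` for every
#'   animal outside the control and model groups.
#' @section Errors: `DegenerateNormalization` when `mean(control)` is 0 in
#'   ratio mode or equals `mean(model)` in corrected mode; `MissingGroup`
#'   when a required group is absent.
#' @examples
#' tbl <- data.frame(animal_id = 1:6,
#'                   group = rep(c("control", "model", "A"), each = 2),
#'                   metric = "FAC", value = c(60, 60, 20, 20, 54, 54))
#' normalizeRescue(tbl)  # E = 0.9 for group A
#' @export
normalizeRescue <- function(table, metric = NULL,
                            mode = c("ratio_to_control", "baseline_corrected"),
                            orientation = c("higher_better", "lower_better"),
                            clip = FALSE,
                            controlGroup = "control", modelGroup = "model") {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  stopifnot(all(c("animal_id", "group", "value") %in% names(table)))
  if (!is.null(metric)) table <- table[table$metric == metric, , drop = FALSE]
  need <- c(controlGroup, if (mode == "baseline_corrected") modelGroup)
  for (g in need) {
    if (sum(table$group == g) < 2L)
      cqStop("MissingGroup", sprintf("group '%s' needs >= 2 animals", g))
  }
  ctrl <- mean(table$value[table$group == controlGroup])
  trt <- table[!table$group %in% c(controlGroup, modelGroup), , drop = FALSE]
  if (mode == "ratio_to_control") {
    if (abs(ctrl) < .Machine$double.eps)
      cqStop("DegenerateNormalization", "mean(control) is zero")
    E <- if (orientation == "higher_better") trt$value / ctrl
         else ctrl / trt$value
  } else {
    mdl <- mean(table$value[table$group == modelGroup])
    if (abs(ctrl - mdl) < .Machine$double.eps)
      cqStop("DegenerateNormalization",
             "control and model means coincide")
    E <- (trt$value - mdl) / (ctrl - mdl)
  }
  out <- data.frame(animal_id = trt$animal_id, group = trt$group, E = E,
                    clipped = E < 0 | E > 1)
  if (clip) out$E <- pmin(1, pmax(0, out$E))
  out
}

#' Bliss additive threshold
#'
#' Predicted combined effect of two independently acting agents:
#' `E_add = E_A + E_B - E_A * E_B`.  Symmetric, monotone non-decreasing in
#' each argument on [0, 1], with 1 as absorbing element.
#'
#' @param eA,eB single-agent effects (vectorized).
#' @return The additive threshold.
#' @examples
#' blissThreshold(0.6, 0.5)  # 0.8
#' @export
blissThreshold <- function(eA, eB) {
  stopifnot(all(is.finite(eA)), all(is.finite(eB)))
  eA + eB - eA * eB
}

#' Bliss combination index
#'
#' `CI = (E_A + E_B - E_A * E_B) / E_AB`.  CI below 1 means the observed
#' combination effect exceeds the Bliss prediction (synergy); above 1,
#' antagonism.  A zero combination effect leaves CI undefined (`NA`).
#'
#' @param eA,eB single-agent effects.
#' @param eAB observed combination effect.
#' @return The combination index, or `NA` when `eAB` is 0.
#' @examples
#' combinationIndex(0.6, 0.5, 0.9)  # 0.888...
#' @export
combinationIndex <- function(eA, eB, eAB) {
  stopifnot(all(is.finite(eAB)))
  eAdd <- blissThreshold(eA, eB)
  ifelse(abs(eAB) < .Machine$double.eps, NA_real_, eAdd / eAB)
}

#' Test the observed combination effect against the additive prediction
#'
#' Two-sided one-sample t-test of the combination group's per-animal
#' effects against the scalar Bliss threshold.
#'
#' @param values per-animal combination-group effects (length >= 2).
#' @param eAdd scalar additive threshold.
#' @return List `statistic`, `p.value`, `direction`
#'   (sign of `mean(values) - eAdd`), `df`, `degenerate`.
#' @section Warnings: with zero variance the test is undefined; a
#'   `DegenerateTest` warning is issued and `p.value` is `NA`.
#' @export
testVsAdditive <- function(values, eAdd) {
  stopifnot(length(values) >= 2L, length(eAdd) == 1L, is.finite(eAdd))
  direction <- sign(mean(values) - eAdd)
  if (sd(values) < .Machine$double.eps) {
    cqWarn("DegenerateTest", "zero variance in combination group")
    return(list(statistic = NA_real_, p.value = NA_real_,
                direction = direction, df = length(values) - 1L,
                degenerate = TRUE))
  }
  tt <- t.test(values, mu = eAdd)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       direction = direction, df = unname(tt$parameter),
       degenerate = FALSE)
}

#' Bliss-Independence synergy analysis of an effect table
#'
#' For each requested metric: per-animal rescue effects are computed with
#' [normalizeRescue()], the single-agent and combination group effects are
#' their group means, the additive threshold and combination index follow,
#' and [testVsAdditive()] compares the combination group with the additive
#' prediction.  Verdicts: `synergy` when CI < 1 and the test is significant
#' with positive direction; `antagonism` when CI > 1 and significant with
#' negative direction; `undefined` when CI cannot be computed; otherwise
#' `additive`.
#'
#' @param table data.frame `animal_id`, `group`, `metric`, `value`.
#' @param metrics metrics to analyse (default: all present).
#' @param groupA,groupB,groupAB labels of the two single-agent groups and
#'   the combination group.
#' @param mode,orientation,clip,controlGroup,modelGroup passed to
#'   [normalizeRescue()]; `orientation` may be a named vector giving one
#'   orientation per metric.
#' @param alpha significance level for the verdict.
#' @param adjust `"none"` (per-metric p-values, default) or `"BH"` for
#'   Benjamini-Hochberg adjustment across metrics.
#' @return A list of [SynergyResult-class], one per metric.
#' @section Errors: `MissingGroup` when a required group is absent for a
#'   metric.
#' @examples
#' sim <- simulateCohort(cohortDesign(), seed = 3)
#' res <- analyzeSynergy(sim$table)[[1]]
#' res
#' @export
analyzeSynergy <- function(table, metrics = NULL,
                           groupA = "A", groupB = "B", groupAB = "AB",
                           mode = c("ratio_to_control", "baseline_corrected"),
                           orientation = "higher_better",
                           clip = FALSE, controlGroup = "control",
                           modelGroup = "model", alpha = 0.05,
                           adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  stopifnot(all(c("animal_id", "group", "metric", "value") %in% names(table)))
  if (is.null(metrics)) metrics <- unique(table$metric)
  results <- lapply(metrics, function(met) {
    ori <- if (!is.null(names(orientation)) && met %in% names(orientation))
      orientation[[met]] else orientation[[1]]
    sub <- table[table$metric == met, , drop = FALSE]
    for (g in c(controlGroup, modelGroup, groupA, groupB, groupAB)) {
      if (!any(sub$group == g))
        cqStop("MissingGroup",
               sprintf("metric '%s': group '%s' is missing", met, g))
    }
    eff <- normalizeRescue(sub, mode = mode, orientation = ori, clip = clip,
                           controlGroup = controlGroup,
                           modelGroup = modelGroup)
    eA <- mean(eff$E[eff$group == groupA])
    eB <- mean(eff$E[eff$group == groupB])
    abVals <- eff$E[eff$group == groupAB]
    eAB <- mean(abVals)
    eAdd <- blissThreshold(eA, eB)
    ci <- combinationIndex(eA, eB, eAB)
    test <- withCallingHandlers(
      testVsAdditive(abVals, eAdd),
      DegenerateTest = function(w) invokeRestart("muffleWarning"))
    new("SynergyResult", metricName = met, eA = eA, eB = eB, eAB = eAB,
        eAdd = eAdd, ci = ci, statistic = test$statistic,
        pValue = test$p.value, direction = test$direction,
        nAB = length(abVals), alpha = alpha, verdict = "additive",
        effects = eff)
  })
  pvals <- vapply(results, function(r) r@pValue, numeric(1))
  if (adjust == "BH") pvals <- stats::p.adjust(pvals, method = "BH")
  for (i in seq_along(results)) {
    r <- results[[i]]
    r@pValue <- pvals[i]
    sig <- is.finite(pvals[i]) && pvals[i] < alpha
    r@verdict <- if (is.na(r@ci)) "undefined"
      else if (sig && r@direction > 0 && r@ci < 1) "synergy"
      else if (sig && r@direction < 0 && r@ci > 1) "antagonism"
      else "additive"
    results[[i]] <- r
  }
  names(results) <- metrics
  results
}
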