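#' @include conditions.R AllClasses.R
NULL

checkSurvivalRecords <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    cqStop("EmptyData", "no survival records")
  if (!all(c("time_h", "event") %in% names(records)))
    cqStop("ConfigError", "records need columns time_h and event")
  if (any(records$time_h <= 0))
    cqStop("ConfigError", "time_h must be positive")
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' the distinct observed times; censored animals leave the risk set after
#' their censoring time, and censorings tied with deaths are processed
#' after the deaths.  Estimation is delegated to
#' [survival::survfit()].
#'
#' @param records data.frame with columns `time_h` (hours) and `event`
#'   (logical/0-1; `TRUE` = death observed), optionally `group`.
#' @param group when `records` holds several groups, the group to
#'   estimate; `NULL` pools everything (or returns the single group).
#' @return A [SurvivalCurve-class].
#' @examples
#' rec <- data.frame(time_h = c(rep(1, 2), rep(2, 3), rep(3, 5)),
#'                   event = c(rep(TRUE, 5), rep(FALSE, 5)))
#' survivalAt(kaplanMeier(rec), 2)  # 0.5
#' @export
kaplanMeier <- function(records, group = NULL) {
  checkSurvivalRecords(records)
  label <- "all"
  if (!is.null(group)) {
    records <- records[records$group == group, , drop = FALSE]
    checkSurvivalRecords(records)
    label <- group
  } else if ("group" %in% names(records) &&
             length(unique(records$group)) == 1L) {
    label <- as.character(records$group[1])
  }
  sf <- survival::survfit(
    survival::Surv(records$time_h, as.integer(records$event)) ~ 1,
    conf.type = "none")
  new("SurvivalCurve", group = label, time = sf$time, survival = sf$surv,
      nRisk = sf$n.risk, nEvent = sf$n.event, nCensor = sf$n.censor)
}

#' Evaluate a survival curve at given times
#'
#' Right-continuous step-function lookup, with S(t) = 1 before the first
#' observed time.
#'
#' @param curve a [SurvivalCurve-class].
#' @param t times (hours), vectorized.
#' @return Survival probabilities.
#' @export
survivalAt <- function(curve, t) {
  stopifnot(is(curve, "SurvivalCurve"))
  idx <- findInterval(t, curve@time)
  c(1, curve@survival)[idx + 1L]
}

#' Log-rank (Mantel-Cox) comparison of two survival curves
#'
#' At each distinct event time the observed deaths in group A are compared
#' with their expectation under the pooled risk set;
#' `chi2 = (sum O - sum E)^2 / sum V` is referred to a chi-square
#' distribution with 1 degree of freedom.  Computation is delegated to
#' [survival::survdiff()].
#'
#' @param recordsA,recordsB data.frames with columns `time_h` and `event`
#'   for the two groups.
#' @return An object of class `"htest"` with elements `statistic`
#'   (chi-square), `parameter` (df), `p.value` and `degenerate`.
#' @section Warnings: with no events in either group the test is
#'   undefined; a `DegenerateTest` warning is issued and `p.value = 1`
#'   with `statistic = 0` is returned by convention.
#' @examples
#' a <- data.frame(time_h = c(2, 4, 6, 8), event = TRUE)
#' logrankTest(a, a)$p.value  # 1: identical groups
#' @export
logrankTest <- function(recordsA, recordsB) {
  checkSurvivalRecords(recordsA)
  checkSurvivalRecords(recordsB)
  pooled <- data.frame(
    time_h = c(recordsA$time_h, recordsB$time_h),
    event = c(as.integer(recordsA$event), as.integer(recordsB$event)),
    grp = rep(c("A", "B"), c(nrow(recordsA), nrow(recordsB))))
  out <- structure(list(
    statistic = c("chi-square" = 0), parameter = c(df = 1),
    p.value = 1, degenerate = FALSE,
    method = "Log-rank (Mantel-Cox) test",
    data.name = sprintf("%d vs %d records", nrow(recordsA), nrow(recordsB))),
    class = "htest")
  if (sum(pooled$event) == 0L) {
    cqWarn("DegenerateTest", "no events in either group; p = 1 by convention")
    out$degenerate <- TRUE
    return(out)
  }
  sd <- survival::survdiff(survival::Surv(time_h, event) ~ grp, data = pooled)
  if (!is.finite(sd$chisq)) {
    cqWarn("DegenerateTest", "log-rank variance is zero; p = 1 by convention")
    out$degenerate <- TRUE
    return(out)
  }
  out$statistic <- c("chi-square" = unname(sd$chisq))
  out$p.value <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  out
}
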