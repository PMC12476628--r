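test_that("rescue-effect normalization matches the hand examples", {
  tbl <- data.frame(
    animal_id = as.character(1:8),
    group = rep(c("control", "model", "A", "B"), each = 2),
    metric = "FAC",
    value = c(60, 60, 20, 20, 54, 54, 60, 60))
  eff <- normalizeRescue(tbl)
  expect_equal(eff$E[eff$group == "A"], c(0.9, 0.9))       # 54/60
  expect_equal(eff$E[eff$group == "B"], c(1, 1))           # equals control
  effc <- normalizeRescue(tbl, mode = "baseline_corrected")
  expect_equal(effc$E[eff$group == "B"], c(1, 1))
  tbl$value[tbl$group == "A"] <- 20                        # equals model
  effm <- normalizeRescue(tbl, mode = "baseline_corrected")
  expect_equal(effm$E[effm$group == "A"], c(0, 0))
})

test_that("lower-is-better metrics are normalized toward the control", {
  tbl <- data.frame(
    animal_id = as.character(1:8),
    group = rep(c("control", "model", "A", "B"), each = 2),
    metric = "LVIDs",
    value = c(2, 2, 4, 4, 2.5, 2.5, 2, 2))
  # ratio mode inverts the ratio: E = control / value
  eff <- normalizeRescue(tbl, orientation = "lower_better")
  expect_equal(eff$E[eff$group == "A"], c(0.8, 0.8))
  expect_equal(eff$E[eff$group == "B"], c(1, 1))
  # corrected mode maps model -> 0, control -> 1 regardless of orientation
  effc <- normalizeRescue(tbl, mode = "baseline_corrected",
                          orientation = "lower_better")
  expect_equal(effc$E[effc$group == "A"], c(0.75, 0.75))
})

test_that("degenerate normalizations and clipping are handled", {
  tbl <- data.frame(animal_id = as.character(1:6),
                    group = rep(c("control", "model", "A"), each = 2),
                    metric = "m", value = c(0, 0, 1, 1, 2, 2))
  expect_error(normalizeRescue(tbl), class = "DegenerateNormalization")
  tbl2 <- tbl; tbl2$value <- c(5, 5, 5, 5, 9, 9)
  expect_error(normalizeRescue(tbl2, mode = "baseline_corrected"),
               class = "DegenerateNormalization")
  tbl3 <- tbl; tbl3$value <- c(4, 4, 1, 1, 6, 6)
  eff <- normalizeRescue(tbl3, clip = TRUE)
  expect_equal(eff$E[eff$group == "A"], c(1, 1))
  expect_true(all(eff$clipped[eff$group == "A"]))
  expect_error(normalizeRescue(tbl3[tbl3$group != "control", ]),
               class = "MissingGroup")
})

test_that("Bliss threshold identities hold on random grids", {
  expect_equal(blissThreshold(0, 0), 0)
  expect_equal(blissThreshold(1, 0.37), 1)
  expect_equal(blissThreshold(0.6, 0.5), 0.8)
  withr::with_seed(1, {
    eA <- runif(2000); eB <- runif(2000)
    eAdd <- blissThreshold(eA, eB)
    expect_equal(eAdd, blissThreshold(eB, eA))             # symmetric
    expect_true(all(eAdd >= pmax(eA, eB) - 1e-12))         # dominates
    expect_true(all(eAdd >= 0 & eAdd <= 1))                # bounded
    # monotone in each argument
    expect_true(all(blissThreshold(pmin(eA + 0.05, 1), eB) >= eAdd - 1e-12))
    # CI = 1 exactly when the observed effect equals the threshold
    expect_equal(combinationIndex(eA, eB, eAdd), rep(1, 2000),
                 tolerance = 1e-12)
  })
})

test_that("combination index follows the printed definition", {
  expect_equal(combinationIndex(0.6, 0.5, 0.9), 0.8 / 0.9)
  expect_true(is.na(combinationIndex(0.6, 0.5, 0)))
  expect_equal(combinationIndex(0.6, 0.5, 0.8), 1)
})

test_that("the observed-vs-additive t-test behaves at its boundaries", {
  # symmetric about the null: t = 0, p = 1
  res <- testVsAdditive(c(0.7, 0.9), 0.8)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_equal(res$direction, 0)
  # zero variance: degenerate, p undefined
  expect_warning(dg <- testVsAdditive(rep(0.9, 4), 0.8),
                 class = "DegenerateTest")
  expect_true(is.na(dg$p.value))
  expect_true(dg$degenerate)
  # power: N(0.9, 0.05^2), n = 10 against 0.8 rejects in >= 95% of seeds
  rejections <- vapply(1:200, function(s) {
    vals <- withr::with_seed(s, rnorm(10, 0.9, 0.05))
    testVsAdditive(vals, 0.8)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("synergy analysis round-trips simulated cohorts", {
  mk <- function(gamma, sd) cohortDesign(
    control = c(n = 10, mean = 1, sd = sd),
    model = c(n = 10, mean = 0.2, sd = sd),
    treatments = data.frame(name = c("A", "B"), n = 10,
                            trueE = c(0.6, 0.5), sd = sd),
    combination = c(n = 10, gamma = gamma, sd = sd))
  # noise-free: CI exact, additive verdict at gamma = 1
  r0 <- analyzeSynergy(simulateCohort(mk(1.125, 0), seed = 1)$table)[[1]]
  expect_equal(combinationIndexOf(r0), 0.8 / 0.9, tolerance = 1e-12)
  r1 <- analyzeSynergy(simulateCohort(mk(1, 0), seed = 1)$table)[[1]]
  expect_equal(combinationIndexOf(r1), 1, tolerance = 1e-12)
  expect_equal(verdict(r1), "additive")
  # noisy recovery: mean CI within 0.05 of truth over 50 cohorts
  for (gamma in c(0.8, 1.25)) {
    sims <- lapply(1:50, function(s) simulateCohort(mk(gamma, 0.05), seed = s))
    cis <- vapply(sims, function(sm)
      combinationIndexOf(analyzeSynergy(sm$table)[[1]]), numeric(1))
    expect_lt(abs(mean(cis) - sims[[1]]$trueCI), 0.05)
  }
})

test_that("missing groups and undefined CI are reported", {
  sim <- simulateCohort(cohortDesign(), seed = 2)
  tab <- sim$table[sim$table$group != "model", ]
  expect_error(analyzeSynergy(tab), class = "MissingGroup")
  # zero combination effect -> undefined verdict
  tab2 <- sim$table
  tab2$value[tab2$group == "AB"] <- 0
  r <- analyzeSynergy(tab2)[[1]]
  expect_equal(verdict(r), "undefined")
  expect_true(is.na(combinationIndexOf(r)))
})

test_that("strong built-in synergy is detected as synergy", {
  d <- cohortDesign(combination = c(n = 10, gamma = 1.2, sd = 0.02),
                    control = c(n = 10, mean = 1, sd = 0.02),
                    model = c(n = 10, mean = 0.2, sd = 0.02),
                    treatments = data.frame(name = c("A", "B"), n = 10,
                                            trueE = c(0.5, 0.4), sd = 0.02))
  hits <- vapply(1:20, function(s) {
    r <- analyzeSynergy(simulateCohort(d, seed = s)$table)[[1]]
    verdict(r) == "synergy" && combinationIndexOf(r) < 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("CI is invariant to uniform rescaling of the raw metric", {
  sim <- simulateCohort(cohortDesign(), seed = 4)
  r1 <- analyzeSynergy(sim$table)[[1]]
  scaled <- sim$table
  scaled$value <- scaled$value * 37.5
  r2 <- analyzeSynergy(scaled)[[1]]
  expect_equal(combinationIndexOf(r1), combinationIndexOf(r2),
               tolerance = 1e-12)
  expect_equal(pValue(r1), pValue(r2), tolerance = 1e-9)
})
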