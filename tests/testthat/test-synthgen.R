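test_that("contraction waveform honours the phase convention and period", {
  p <- defaultParams()
  period <- 60 / p@bpm
  expect_equal(contractionWaveform(0, p), 0)
  expect_equal(contractionWaveform(p@systolicFraction * period, p), 1)
  expect_equal(contractionWaveform(period, p), 0)
  # periodic and continuous
  t <- seq(0, 2 * period, by = 0.001)
  s <- contractionWaveform(t, p)
  expect_equal(contractionWaveform(t + 3 * period, p), s, tolerance = 1e-12)
  expect_lt(max(abs(diff(s))), 0.05)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("waveform mean over one period is resolution independent", {
  p <- defaultParams()
  period <- 60 / p@bpm
  m1 <- mean(contractionWaveform(seq(0, period, length.out = 101)[-101], p))
  m2 <- mean(contractionWaveform(seq(0, period, length.out = 2001)[-2001], p))
  expect_equal(m1, m2, tolerance = 1e-3)
})

test_that("analytic metrics evaluate the printed formulas", {
  # identity case: no contraction
  p0 <- heartSimParams(edSemiAxes = c(20, 20), contractionFrac = c(0, 0))
  m0 <- analyticMetrics(p0)
  expect_equal(fac(m0), 0)
  expect_equal(fs(m0), 0)
  expect_equal(sv(m0), 0)
  expect_equal(co(m0), 0)
  # FAC from areas: EDA 1000, ESA 600 -> 40%
  expect_equal(computeFAC(1000, 600), 40)
  # ellipsoid volumes with semi-axes 10,6 (ED) and 8,5 (ES)
  vols <- computeVolumes(10, 6, 8, 5, bpm = 120)
  expect_equal(vols[["sv"]], 4 * pi / 3 * (10 * 36 - 8 * 25))
  expect_equal(vols[["co"]], vols[["sv"]] * 120)
  # BPM and derived quantities propagate from the generator
  m <- analyticMetrics(defaultParams())
  expect_equal(bpm(m), 120)
  expect_equal(co(m), sv(m) * 120)
  expect_equal(fac(m), 40, tolerance = 1e-12)
})

test_that("simulated frames match the analytic chamber area at ED", {
  p <- heartSimParams(psfSigmaPx = 0)
  v <- simulateVideo(p, seed = 11)
  gt <- groundTruth(v)
  edFrame <- which.max(gt$area)
  count <- sum(frames(v)[, , edFrame] > p@backgroundLevel + 0.5)
  expect_equal(count, pi * 30 * 18, tolerance = 0.02)
  # ground truth oscillates between the analytic extremes
  expect_equal(max(gt$area), pi * 30 * 18, tolerance = 1e-9)
  expect_equal(min(gt$area), pi * 30 * 18 * prod(1 - p@contractionFrac),
               tolerance = 1e-3)
})

test_that("video simulation is deterministic under a fixed seed", {
  p <- heartSimParams(durationS = 0.5, noiseGaussianSd = 0.1,
                      noisePoissonScale = 200, jitterPx = 1)
  v1 <- simulateVideo(p, seed = 99)
  v2 <- simulateVideo(p, seed = 99)
  expect_identical(frames(v1), frames(v2))
  v3 <- simulateVideo(p, seed = 100)
  expect_false(identical(frames(v1), frames(v3)))
})

test_that("a non-contracting heart yields no detectable cycles", {
  p <- heartSimParams(contractionFrac = c(0, 0), durationS = 1)
  v <- simulateVideo(p, seed = 1)
  expect_error(quantifyVideo(v), class = "InsufficientCycles")
})

test_that("geometry exceeding the frame is rejected", {
  expect_error(heartSimParams(imageShape = c(64L, 64L),
                              edSemiAxes = c(40, 20)),
               class = "ConfigError")
  expect_error(heartSimParams(contractionFrac = c(1, 0.5)),
               class = "ConfigError")
})

test_that("cohort simulation inverts the normalization exactly at sd 0", {
  d <- cohortDesign(control = c(n = 5, mean = 2, sd = 0),
                    model = c(n = 5, mean = 0.5, sd = 0),
                    treatments = data.frame(name = c("A", "B"), n = 5,
                                            trueE = c(0.6, 0.5), sd = 0),
                    combination = c(n = 5, gamma = 1.125, sd = 0))
  sim <- simulateCohort(d, seed = 1)
  expect_equal(sim$trueCI, 0.8 / 0.9)
  eff <- normalizeRescue(sim$table)
  expect_equal(mean(eff$E[eff$group == "A"]), 0.6, tolerance = 1e-12)
  expect_equal(mean(eff$E[eff$group == "AB"]), 0.9, tolerance = 1e-12)
  # gamma = 1 means exact additivity
  d1 <- cohortDesign(combination = c(n = 10, gamma = 1, sd = 0.05))
  expect_equal(simulateCohort(d1, seed = 1)$trueCI, 1)
  # deterministic under seed
  s1 <- simulateCohort(cohortDesign(), seed = 7)
  s2 <- simulateCohort(cohortDesign(), seed = 7)
  expect_identical(s1$table, s2$table)
  expect_error(cohortDesign(combination = c(n = 10, gamma = 0, sd = 0)),
               class = "ConfigError")
})

test_that("baseline-corrected designs also round-trip", {
  d <- cohortDesign(normalizationMode = "baseline_corrected",
                    control = c(n = 5, mean = 60, sd = 0),
                    model = c(n = 5, mean = 20, sd = 0),
                    treatments = data.frame(name = c("A", "B"), n = 5,
                                            trueE = c(0.6, 0.5), sd = 0),
                    combination = c(n = 5, gamma = 1, sd = 0))
  sim <- simulateCohort(d, seed = 2)
  eff <- normalizeRescue(sim$table, mode = "baseline_corrected")
  expect_equal(mean(eff$E[eff$group == "B"]), 0.5, tolerance = 1e-12)
  expect_equal(mean(eff$E[eff$group == "AB"]), 0.8, tolerance = 1e-12)
})

test_that("survival simulation follows the inspection-grid convention", {
  # zero hazard: everyone right-censored at the horizon
  p0 <- survivalSimParams(groups = data.frame(name = "g", n = 20, hazard = 0))
  s0 <- simulateSurvival(p0, seed = 1)
  expect_true(all(!s0$event))
  expect_true(all(s0$time_h == 32))
  # times are positive multiples of the grid
  p <- survivalSimParams()
  s <- simulateSurvival(p, seed = 3)
  expect_true(all(s$time_h > 0 & s$time_h <= 32))
  expect_true(all(abs(s$time_h / 0.5 - round(s$time_h / 0.5)) < 1e-9))
  # exponential median: hazard ln2/8 -> about half the events by 8 h
  pm <- survivalSimParams(groups = data.frame(name = "m", n = 2000,
                                              hazard = log(2) / 8))
  sm <- simulateSurvival(pm, seed = 5)
  frac <- mean(sm$time_h <= 8 & sm$event)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000) + 0.05)
  # determinism
  expect_identical(simulateSurvival(p, seed = 9),
                   simulateSurvival(p, seed = 9))
})

test_that("empirical survival converges to the exponential curve", {
  par <- survivalSimParams(groups = data.frame(name = "g", n = 2000,
                                               hazard = log(2) / 8))
  s <- simulateSurvival(par, seed = 21)
  km <- kaplanMeier(s)
  grid <- seq(0.5, 32, by = 0.5)
  dist <- max(abs(survivalAt(km, grid) - exp(-log(2) / 8 * grid)))
  expect_lt(dist, 0.05)
})
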