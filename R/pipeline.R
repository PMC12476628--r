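#' @include io.R synthgen.R cardiometrics.R synergy.R survstats.R
NULL

# schema: known keys with defaults; unknown keys are rejected
configSchema <- function() {
  list(
    seed = 1L,
    fps = 100,
    pixel_size_um = NA_real_,
    simulate = list(
      image_shape = c(128L, 128L), duration_s = 2, bpm = 120,
      orientation_deg = 0, ed_semi_axes = c(30, 18),
      contraction_frac = rep(1 - sqrt(0.6), 2), systolic_fraction = 0.4,
      render_mode = "filled", wall_thickness_px = 4, psf_sigma_px = 1,
      background_level = 0.1, signal_level = 1, noise_gaussian_sd = 0,
      noise_poisson_scale = 0, jitter_px = 0),
    segmentation = list(sigma = 1, threshold = NULL, min_area = 20,
                        mode = NULL, close_size = 5),
    cycles = list(smooth_window = 3, min_prominence = 0.1, min_cycles = 4,
                  bpm_method = "count", average = "mean"),
    axis_convention = "semi",
    synergy = list(mode = "ratio_to_control", orientation = "higher_better",
                   clip = FALSE, alpha = 0.05, adjust = "none",
                   group_a = "A", group_b = "B", group_ab = "AB",
                   control_group = "control", model_group = "model"),
    survival = list(horizon_h = 32, grid_h = 0.5, reference_group = "model")
  )
}

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    cqStop("ConfigError", sprintf("unknown config key%s: %s",
      if (length(unknown) > 1) "s" else "",
      paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]],
                                   paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Build a validated run configuration
#'
#' Materializes the full default configuration, overlays user settings
#' (from a YAML file or a list) and validates the values.  Unknown keys
#' are rejected by name so typos fail loudly.
#'
#' @param config `NULL` for pure defaults, a path to a YAML file, or a
#'   named list of overrides.
#' @return A list of class `"RunConfig"` with all defaults materialized.
#' @section Errors: `ConfigError` naming the offending key or field.
#' @examples
#' cfg <- runConfig(list(fps = 50))
#' cfg$fps
#' @export
runConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      cqStop("InputError", sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- mergeConfig(configSchema(), config)
  if (!is.numeric(cfg$fps) || cfg$fps <= 0)
    cqStop("ConfigError", "fps must be a positive number")
  if (!is.numeric(cfg$simulate$duration_s) || cfg$simulate$duration_s <= 0)
    cqStop("ConfigError", "simulate.duration_s must be positive")
  if (!cfg$axis_convention %in% c("semi", "literal"))
    cqStop("ConfigError", "axis_convention must be 'semi' or 'literal'")
  if (cfg$synergy$alpha <= 0 || cfg$synergy$alpha >= 1)
    cqStop("ConfigError", "synergy.alpha must lie in (0, 1)")
  class(cfg) <- c("RunConfig", "list")
  cfg
}

paramsFromConfig <- function(cfg) {
  s <- cfg$simulate
  heartSimParams(
    imageShape = as.integer(s$image_shape), fps = cfg$fps,
    durationS = s$duration_s, bpm = s$bpm,
    orientationDeg = s$orientation_deg, edSemiAxes = s$ed_semi_axes,
    contractionFrac = s$contraction_frac,
    systolicFraction = s$systolic_fraction, renderMode = s$render_mode,
    wallThicknessPx = s$wall_thickness_px, psfSigmaPx = s$psf_sigma_px,
    backgroundLevel = s$background_level, signalLevel = s$signal_level,
    noiseGaussianSd = s$noise_gaussian_sd,
    noisePoissonScale = s$noise_poisson_scale, jitterPx = s$jitter_px)
}

segConfigFromConfig <- function(cfg, video = NULL) {
  mode <- cfg$segmentation$mode
  if (is.null(mode))
    mode <- if (!is.null(video) && !is.null(video@params))
      video@params@renderMode else "filled"
  segmentationConfig(sigma = cfg$segmentation$sigma,
                     threshold = cfg$segmentation$threshold,
                     minArea = cfg$segmentation$min_area,
                     mode = mode, closeSize = cfg$segmentation$close_size)
}

writeManifest <- function(outDir, cfg, seed, files) {
  sums <- tools::md5sum(file.path(outDir, files))
  manifest <- list(seed = seed,
                   config = unclass(cfg),
                   files = as.list(setNames(unname(sums), files)))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

#' Generate a complete synthetic dataset
#'
#' Writes a simulated heart-beating video (multi-page 16-bit TIFF), its
#' per-frame ground truth, a synergy cohort table with its true effects,
#' and a survival table, plus a manifest echoing the configuration, the
#' seed and MD5 checksums of every artifact.
#'
#' @param config see [runConfig()].
#' @param outDir output directory (created if needed).
#' @param seed integer seed; overrides the config's seed when given.
#' @return Invisibly, the manifest list.
#' @export
runSimulate <- function(config = NULL, outDir, seed = NULL) {
  cfg <- runConfig(config)
  if (is.null(seed)) seed <- cfg$seed
  seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir))
    cqStop("IOError", sprintf("cannot create output directory: %s", outDir))

  video <- simulateVideo(paramsFromConfig(cfg), seed = seed,
                         pixelSizeUm = cfg$pixel_size_um)
  writeHeartVideo(video, file.path(outDir, "video.tif"))
  writeTableCSV(groundTruth(video), file.path(outDir, "ground_truth.csv"))

  cohort <- simulateCohort(cohortDesign(
    normalizationMode = cfg$synergy$mode), seed = seed)
  writeTableCSV(cohort$table, file.path(outDir, "cohort.csv"))
  writeResultJSON(list(true_CI = cohort$trueCI,
                       true_effects = as.list(cohort$trueEffects)),
                  file.path(outDir, "cohort_truth.json"))

  surv <- simulateSurvival(survivalSimParams(
    horizonH = cfg$survival$horizon_h, gridH = cfg$survival$grid_h),
    seed = seed)
  writeTableCSV(surv, file.path(outDir, "survival.csv"))

  writeManifest(outDir, cfg, seed,
                c("video.tif", "ground_truth.csv", "cohort.csv",
                  "cohort_truth.json", "survival.csv"))
}

#' Quantify a video file end to end
#'
#' Reads the video, runs [quantifyVideo()] under the given configuration
#' and writes `metrics.json` plus the per-cycle table `per_cycle.csv`.
#'
#' @param videoPath TIFF stack or PNG directory.
#' @param config see [runConfig()].
#' @param outDir output directory.
#' @return The [CardiacMetrics-class], invisibly.
#' @export
runQuantify <- function(videoPath, config = NULL, outDir) {
  cfg <- runConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  video <- readHeartVideo(videoPath, fps = cfg$fps,
                          pixelSizeUm = cfg$pixel_size_um)
  metrics <- quantifyVideo(video, cfg = segConfigFromConfig(cfg, video),
                           smoothWindow = cfg$cycles$smooth_window,
                           minProminence = cfg$cycles$min_prominence,
                           minCycles = cfg$cycles$min_cycles,
                           convention = cfg$axis_convention,
                           bpmMethod = cfg$cycles$bpm_method,
                           average = cfg$cycles$average)
  writeResultJSON(c(metricsAsList(metrics), list(config = unclass(cfg))),
                  file.path(outDir, "metrics.json"))
  writeTableCSV(perCycle(metrics), file.path(outDir, "per_cycle.csv"))
  invisible(metrics)
}

#' Run the Bliss synergy analysis on an effect table file
#'
#' @param tablePath CSV with columns `animal_id`, `group`, `metric`,
#'   `value`.
#' @param config see [runConfig()].
#' @param outDir output directory; receives `synergy.json` and
#'   `synergy.csv` (one row per metric, additive threshold included).
#' @return The list of [SynergyResult-class], invisibly.
#' @export
runSynergy <- function(tablePath, config = NULL, outDir) {
  cfg <- runConfig(config)
  if (!file.exists(tablePath))
    cqStop("InputError", sprintf("table not found: %s", tablePath))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tab <- read.csv(tablePath)
  sy <- cfg$synergy
  results <- analyzeSynergy(tab, mode = sy$mode,
                            orientation = sy$orientation, clip = sy$clip,
                            groupA = sy$group_a, groupB = sy$group_b,
                            groupAB = sy$group_ab,
                            controlGroup = sy$control_group,
                            modelGroup = sy$model_group,
                            alpha = sy$alpha, adjust = sy$adjust)
  rows <- lapply(results, function(r)
    as.data.frame(synergyAsList(r), stringsAsFactors = FALSE))
  writeResultJSON(list(results = lapply(results, synergyAsList),
                       config = unclass(cfg)),
                  file.path(outDir, "synergy.json"))
  writeTableCSV(do.call(rbind, rows), file.path(outDir, "synergy.csv"))
  invisible(results)
}

#' Run the survival analysis on a records file
#'
#' Computes a Kaplan-Meier curve per group and log-rank tests of every
#' group against the configured reference group.
#'
#' @param tablePath CSV with columns `id`, `group`, `time_h`, `event`.
#' @param config see [runConfig()]; `survival.reference_group` names the
#'   comparison baseline.
#' @param outDir output directory; receives `km_curves.csv` (step
#'   functions for plotting) and `survival_tests.json`.
#' @return Invisibly, a list with the curves and the tests.
#' @export
runSurvival <- function(tablePath, config = NULL, outDir) {
  cfg <- runConfig(config)
  if (!file.exists(tablePath))
    cqStop("InputError", sprintf("table not found: %s", tablePath))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rec <- read.csv(tablePath)
  if (!"group" %in% names(rec)) rec$group <- "all"
  groups <- unique(rec$group)
  curves <- lapply(groups, function(g) kaplanMeier(rec, group = g))
  names(curves) <- groups
  curveRows <- do.call(rbind, lapply(curves, function(cu)
    data.frame(group = cu@group, time_h = cu@time, survival = cu@survival,
               n_risk = cu@nRisk, n_event = cu@nEvent,
               n_censor = cu@nCensor)))
  writeTableCSV(curveRows, file.path(outDir, "km_curves.csv"))
  ref <- cfg$survival$reference_group
  if (!ref %in% groups) ref <- groups[1]
  tests <- lapply(setdiff(groups, ref), function(g) {
    lt <- withCallingHandlers(
      logrankTest(rec[rec$group == ref, ], rec[rec$group == g, ]),
      DegenerateTest = function(w) invokeRestart("muffleWarning"))
    list(reference = ref, group = g,
         chi_square = unname(lt$statistic), p_value = lt$p.value,
         degenerate = lt$degenerate)
  })
  writeResultJSON(list(tests = tests, config = unclass(cfg)),
                  file.path(outDir, "survival_tests.json"))
  invisible(list(curves = curves, tests = tests))
}
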