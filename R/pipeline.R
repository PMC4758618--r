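# reference arm per channel: the first arm expressing only that channel
# (for dual-tag competition scenarios the haploid single-tag strain);
# otherwise the first arm
referenceArmIndex <- function(scenario, channel) {
  fr <- scenario@arms[[paste0("frac_", channel)]]
  i <- which(fr == 1)
  if (length(i)) i[1] else 1L
}

applyOverrides <- function(fun, overrides) do.call(fun, overrides)

#' Run the full analysis pipeline on a scenario
#'
#' Simulation, detection, dual-ROI quantitation, (for morphometry
#' scenarios) patch-based size fitting, control normalization, and
#' population statistics, end to end. With \code{outDir} set, writes the
#' stacks (multi-page TIFF per arm and channel), ground truth and
#' measurement CSVs, a legend-style text report, the exact run
#' configuration, and a log; re-running the same configuration
#' reproduces the outputs bit-exactly.
#'
#' @param config a \code{\link{runConfig}}, or a scenario preset
#'   name / \linkS4class{GenotypeScenario} (with further arguments
#'   below).
#' @param seed integer seed (mandatory unless carried by \code{config}).
#' @param nFoci foci per arm; \code{NULL} for the scenario default.
#' @param optics an \linkS4class{OpticsModel}.
#' @param geometry an \code{\link{roiGeometry}}.
#' @param detection a \code{\link{detectionParams}} (its \code{maxSpots}
#'   is capped at the planted focus count per stack).
#' @param outDir optional output directory.
#' @return a \code{ScenarioRun}: list with \code{measurements} (per
#'   focus and channel: corrected and normalized intensities),
#'   \code{sizes} (morphometry scenarios), \code{summaries} (per arm:
#'   legend-style mean±sd), \code{comparisons} (Welch t vs the reference
#'   arm), \code{report} (character lines) and \code{log}.
#' @examples
#' \donttest{
#' run <- runScenario("fig2a_psh1del", seed = 1, nFoci = 40)
#' run$report
#' }
#' @export
runScenario <- function(config, seed = NULL, nFoci = NULL,
                        optics = OpticsModel(),
                        geometry = roiGeometry(),
                        detection = detectionParams(),
                        outDir = NULL) {
  if (inherits(config, "RunConfig")) {
    cfg <- config
    scenario <- scenarioPreset(cfg$scenario)
    seed <- cfg$seed
    nFoci <- cfg$nFoci
    optics <- applyOverrides(OpticsModel, cfg$optics)
    geometry <- applyOverrides(roiGeometry, cfg$geometry)
    detection <- applyOverrides(detectionParams, cfg$detection)
    outDir <- cfg$outDir
  } else {
    scenario <- if (is.character(config)) scenarioPreset(config) else config
    cfg <- runConfig(scenario = scenario@name, seed = seed, nFoci = nFoci,
                     outDir = outDir)
  }
  if (is.null(seed)) kqConfigError("a seed is mandatory")

  sim <- simulateField(scenario, seed = seed, optics = optics,
                       nFoci = nFoci)
  n <- sim$nFoci
  channels <- scenario@channels
  morpho <- scenario@mode == "morphometry"
  log <- c(sprintf("kinetoquant %s",
                   as.character(utils::packageVersion("kinetoquant"))),
           sprintf("scenario %s seed %d nFoci %d", scenario@name, sim$seed, n))

  measurements <- NULL
  sizes <- NULL
  for (arm in sim$arms) {
    det <- detection
    det$maxSpots <- min(det$maxSpots, n)
    sumv <- Reduce(`+`, lapply(arm$grids, intensityValues))
    detGrid <- arm$grids[[1]]
    detGrid@values <- sumv
    cand <- findFoci(detGrid, det)
    log <- c(log, sprintf("arm %-24s detected %d/%d foci",
                          arm$genotype, nrow(cand), n))
    for (ch in channels) {
      meas <- measureFoci(arm$grids[[ch]], cand, geometry)
      meas$genotype <- arm$genotype
      meas$channel <- ch
      measurements <- rbind(measurements, meas)
    }
    if (morpho) {
      sz <- measureFocusSizes(arm$grids[[channels[1]]], cand)
      sz$genotype <- arm$genotype
      sz$channel <- channels[1]
      nfail <- sum(!sz$converged)
      if (nfail > 0)
        log <- c(log, sprintf("arm %-24s %d/%d size fits failed (excluded)",
                              arm$genotype, nfail, nrow(sz)))
      sizes <- rbind(sizes, sz)
    }
  }

  # control normalization per channel
  measurements$normalized <- NA_real_
  measurements$reference <- NA_character_
  for (ch in channels) {
    refGt <- scenario@arms$genotype[referenceArmIndex(scenario, ch)]
    ref <- measurements$corrected[measurements$genotype == refGt &
                                    measurements$channel == ch]
    sel <- measurements$channel == ch
    measurements$normalized[sel] <-
      normalizePopulation(measurements$corrected[sel], ref)
    measurements$reference[sel] <- refGt
  }
  if (morpho) {
    refGt <- scenario@arms$genotype[1]
    ok <- sizes$converged
    refF <- sizes$fwhm_px[ok & sizes$genotype == refGt]
    refH <- sizes$peak_height[ok & sizes$genotype == refGt]
    sizes$fwhm_normalized <- NA_real_
    sizes$height_normalized <- NA_real_
    sizes$fwhm_normalized[ok] <- normalizePopulation(sizes$fwhm_px[ok], refF)
    sizes$height_normalized[ok] <-
      normalizePopulation(sizes$peak_height[ok], refH)
    sizes$reference <- refGt
  }

  # summaries and comparisons
  summaries <- NULL
  comparisons <- list()
  report <- character(0)
  for (ch in channels) {
    refGt <- scenario@arms$genotype[referenceArmIndex(scenario, ch)]
    ref <- measurements$normalized[measurements$genotype == refGt &
                                     measurements$channel == ch]
    for (gt in scenario@arms$genotype) {
      vals <- measurements$normalized[measurements$genotype == gt &
                                        measurements$channel == ch]
      s <- summarizeArm(vals, gt)
      stars <- ""
      if (gt != refGt) {
        cmp <- compareArms(ref, vals)
        comparisons[[paste(ch, gt, sep = ":")]] <- cmp
        stars <- cmp$stars
      }
      summaries <- rbind(summaries, data.frame(
        channel = ch, genotype = gt, metric = "intensity",
        n = s$n, mean = s$mean, sd = s$sd,
        formatted = s$formatted, stars = stars))
      report <- c(report, sprintf("%s %-24s %s%s", ch, gt,
                                  s$formatted, stars))
    }
  }
  if (morpho) {
    refGt <- scenario@arms$genotype[1]
    ok <- sizes$converged
    for (metric in c("fwhm", "peak_height")) {
      col <- if (metric == "fwhm") "fwhm_normalized" else "height_normalized"
      ref <- sizes[[col]][ok & sizes$genotype == refGt]
      for (gt in scenario@arms$genotype) {
        vals <- sizes[[col]][ok & sizes$genotype == gt]
        s <- summarizeArm(vals, gt)
        stars <- ""
        if (gt != refGt) {
          cmp <- compareArms(ref, vals)
          comparisons[[paste(metric, gt, sep = ":")]] <- cmp
          stars <- cmp$stars
        }
        summaries <- rbind(summaries, data.frame(
          channel = channels[1], genotype = gt, metric = metric,
          n = s$n, mean = s$mean, sd = s$sd,
          formatted = s$formatted, stars = stars))
        report <- c(report, sprintf("%s %-24s %s %s%s", channels[1], gt,
                                    metric, s$formatted, stars))
      }
    }
  }

  run <- structure(
    list(scenario = scenario, config = cfg, seed = sim$seed,
         simulation = sim, measurements = measurements, sizes = sizes,
         summaries = summaries, comparisons = comparisons,
         report = report, log = log),
    class = "ScenarioRun")
  if (!is.null(outDir)) writeScenarioRun(run, outDir)
  run
}

#' @export
print.ScenarioRun <- function(x, ...) {
  cat(sprintf("ScenarioRun '%s' (seed %d)\n", x$scenario@name, x$seed))
  cat(paste0("  ", x$report, "\n"), sep = "")
  invisible(x)
}

#' Recovered fold changes of a run
#'
#' Mean control-normalized value per arm, channel and metric -- the
#' quantity compared against a scenario's planted folds.
#'
#' @param run a \code{ScenarioRun}.
#' @return data.frame: \code{channel}, \code{genotype}, \code{metric},
#'   \code{n}, \code{mean}, \code{sd}, \code{formatted}, \code{stars}.
#' @export
foldEstimates <- function(run) run$summaries

writeScenarioRun <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (arm in run$simulation$arms)
    for (ch in names(arm$grids))
      writeStack(arm$grids[[ch]],
                 file.path(outDir, sprintf("%s_%s.tiff", arm$genotype, ch)))
  writeCSV <- function(df, name)
    utils::write.csv(df, file.path(outDir, name), row.names = FALSE)
  writeCSV(run$simulation$truth, "truth.csv")
  writeCSV(run$measurements, "measurements.csv")
  if (!is.null(run$sizes)) writeCSV(run$sizes, "sizes.csv")
  writeCSV(run$summaries, "summaries.csv")
  writeLines(run$report, file.path(outDir, "report.txt"))
  writeLines(run$log, file.path(outDir, "log.txt"))
  writeRunConfig(run$config, file.path(outDir, "config.yaml"))
  invisible(outDir)
}
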