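## Pipeline stages: each cmd* function takes a run configuration (a plain
## named list, typically loaded from YAML), writes its outputs plus a
## manifest, and returns the paths invisibly.  Reruns with the same
## configuration and seed are bit-identical for deterministic stages.

#' Load a run configuration
#'
#' Reads a YAML run configuration and fills defaults.  A seed is mandatory
#' for any stochastic stage.
#'
#' @param path YAML file, or \code{NULL} to start from defaults.
#' @param ... named overrides.
#' @return a named list.
#' @export
runConfig <- function(path = NULL, ...) {
  cfg <- list(
    outDir = "triloci_out",
    seed = NULL,
    nNuclei = 75L,
    species = "pig",
    nucleusRadiusMean = 5,
    nucleusRadiusSd = 0.25,
    fracDecompacted = 0.5,
    spotRadius = 0.25,
    activationPair = c("classI", "classIII"),
    activationShift = 0.6,
    measurementNoiseSd = 0.05,
    separabilityMargin = 0.2,
    szMethod = "mle",
    quantile = 0,
    inputResting = NULL,
    inputActivated = NULL
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

.writeManifest <- function(cfg, stage, inputs, outputs) {
  man <- list(stage = stage,
              inputs = inputs,
              outputs = outputs,
              parameters = cfg[setdiff(names(cfg), c("outDir"))],
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("TriLociFISH")))
  path <- file.path(cfg$outDir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

.stageGuard <- function(cfg, stage, outputs, expr) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  tryCatch(expr, error = function(e) {
    unlink(file.path(cfg$outDir, outputs))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

.loadPopulations <- function(cfg) {
  paths <- c(resting = cfg$inputResting %||%
               file.path(cfg$outDir, "population_resting.tsv"),
             activated = cfg$inputActivated %||%
               file.path(cfg$outDir, "population_activated.tsv"))
  pops <- list()
  for (cond in names(paths))
    if (file.exists(paths[[cond]]))
      pops[[cond]] <- readSpotTable(paths[[cond]])
  if (!length(pops))
    stop("no input populations found (looked for ",
         paste(paths, collapse = ", "), ")")
  attr(pops, "paths") <- paths
  pops
}

#' Simulate stage: write populations and ground truth
#'
#' @param cfg run configuration from [runConfig()].
#' @param conditions conditions to simulate.
#' @return output paths, invisibly.
#' @export
cmdSimulate <- function(cfg, conditions = c("resting", "activated")) {
  if (is.null(cfg$seed)) stop("cmdSimulate requires a seed")
  outs <- c(paste0("population_", conditions, ".tsv"),
            paste0("ground_truth_", conditions, ".json"))
  .stageGuard(cfg, "simulate", outs, {
    sim <- simulationConfig(
      nNuclei = cfg$nNuclei, seed = cfg$seed, species = cfg$species,
      nucleusRadiusMean = cfg$nucleusRadiusMean,
      nucleusRadiusSd = cfg$nucleusRadiusSd,
      fracDecompacted = cfg$fracDecompacted,
      spotRadius = cfg$spotRadius,
      activationPair = cfg$activationPair,
      activationShift = cfg$activationShift,
      measurementNoiseSd = cfg$measurementNoiseSd)
    paths <- character()
    for (cond in conditions) {
      pop <- simulatePopulation(sim, cond)
      tsv <- file.path(cfg$outDir, paste0("population_", cond, ".tsv"))
      gtj <- file.path(cfg$outDir, paste0("ground_truth_", cond, ".json"))
      writeSpotTable(pop, tsv, groundTruthPath = gtj)
      paths <- c(paths, tsv, gtj)
    }
    man <- .writeManifest(cfg, "simulate", inputs = list(), outputs = paths)
    invisible(c(paths, man))
  })
}

#' Radial stage: radial tables, null comparison, cumulative plots
#'
#' @param cfg run configuration.
#' @return output paths, invisibly.
#' @export
cmdRadial <- function(cfg) {
  outs <- c("radial_positions.tsv", "radial_tests.tsv", "radial_cdf.png")
  .stageGuard(cfg, "radial", outs, {
    pops <- .loadPopulations(cfg)
    rad <- do.call(rbind, lapply(pops, radialPositions))
    tsv <- file.path(cfg$outDir, "radial_positions.tsv")
    utils::write.table(rad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- list()
    for (cond in unique(rad$condition)) {
      sub <- rad[rad$condition == cond, ]
      pw <- pairwiseComparisons(sub$radial, sub$channel)
      pw$condition <- cond
      tests[[cond]] <- pw
    }
    ttsv <- file.path(cfg$outDir, "radial_tests.tsv")
    utils::write.table(do.call(rbind, tests), ttsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    png <- file.path(cfg$outDir, "radial_cdf.png")
    p <- plotCumulativeFrequency(rad$radial,
                                 paste(rad$condition, rad$channel),
                                 xlab = "normalized radial position")
    ggplot2::ggsave(png, p, width = 7, height = 5, dpi = 150)
    man <- .writeManifest(cfg, "radial", attr(pops, "paths"),
                          c(tsv, ttsv, png))
    invisible(c(tsv, ttsv, png, man))
  })
}

#' Distances stage: triangle metrics and condition comparisons
#'
#' @param cfg run configuration.
#' @return output paths, invisibly.
#' @export
cmdDistances <- function(cfg) {
  outs <- c("triangle_metrics.tsv", "distance_tests.tsv")
  .stageGuard(cfg, "distances", outs, {
    pops <- .loadPopulations(cfg)
    tm <- do.call(rbind, lapply(pops, triangleMetrics,
                                separabilityMargin = cfg$separabilityMargin))
    tsv <- file.path(cfg$outDir, "triangle_metrics.tsv")
    utils::write.table(tm, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- tsv
    if (all(c("resting", "activated") %in% tm$condition)) {
      rows <- lapply(c(a = "a", b = "b", c = "c"), function(m) {
        r <- compareSamples(tm[tm$condition == "resting", m],
                            tm[tm$condition == "activated", m])
        data.frame(measure = m, statistic = r$statistic,
                   p.value = r$p.value,
                   mean_resting = r$mean_x, mean_activated = r$mean_y,
                   n_resting = r$n_x, n_activated = r$n_y,
                   stringsAsFactors = FALSE)
      })
      ttsv <- file.path(cfg$outDir, "distance_tests.tsv")
      utils::write.table(do.call(rbind, rows), ttsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, ttsv)
    }
    man <- .writeManifest(cfg, "distances", attr(pops, "paths"), paths)
    invisible(c(paths, man))
  })
}

#' Alleles stage: pattern counts and chi-squared reports
#'
#' @param cfg run configuration.
#' @return output paths, invisibly.
#' @export
cmdAlleles <- function(cfg) {
  outs <- c("pattern_counts.tsv", "pattern_tests.json", "pattern_bars.png")
  .stageGuard(cfg, "alleles", outs, {
    pops <- .loadPopulations(cfg)
    pcs <- lapply(pops, patternCounts,
                  separabilityMargin = cfg$separabilityMargin)
    rows <- lapply(names(pcs), function(cond) {
      v <- as.vector(pcs[[cond]])
      data.frame(condition = cond, n_CC = v["CC"], n_CD = v["CD"],
                 n_DD = v["DD"], n_excluded = pcs[[cond]]@nExcluded,
                 stringsAsFactors = FALSE)
    })
    tsv <- file.path(cfg$outDir, "pattern_counts.tsv")
    utils::write.table(do.call(rbind, rows), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tests <- lapply(pcs, function(pc) {
      if (sum(as.vector(pc)) == 0)
        return(list(note = "no informative nuclei (all excluded)"))
      suppressWarnings(chisqGivenProbs(pc)[c("statistic", "df", "p.value")])
    })
    if (all(c("resting", "activated") %in% names(pcs)) &&
        all(vapply(pcs, function(pc) sum(as.vector(pc)) > 0, logical(1))))
      tests$condition_comparison <- suppressWarnings(compareConditions(
        pcs$resting, pcs$activated)[c("statistic", "df", "p.value")])
    js <- file.path(cfg$outDir, "pattern_tests.json")
    jsonlite::write_json(tests, js, auto_unbox = TRUE, digits = NA)
    png <- file.path(cfg$outDir, "pattern_bars.png")
    p <- do.call(plotPatternBars, pcs)
    ggplot2::ggsave(png, p, width = 6, height = 4, dpi = 150)
    man <- .writeManifest(cfg, "alleles", attr(pops, "paths"),
                          c(tsv, js, png))
    invisible(c(tsv, js, png, man))
  })
}

#' Survival-zone stage: fit, reconstruct, plot
#'
#' @param cfg run configuration.
#' @return output paths, invisibly.
#' @export
cmdFitSZ <- function(cfg) {
  outs <- c("survival_zones_resting.json", "survival_zones_activated.json",
            "survival_zones.png")
  .stageGuard(cfg, "fit_sz", outs, {
    pops <- .loadPopulations(cfg)
    paths <- character()
    for (cond in names(pops)) {
      triples <- alleleDistanceTriples(
        pops[[cond]], separabilityMargin = cfg$separabilityMargin)
      model <- fitSurvivalZones(triples, method = cfg$szMethod,
                                q = cfg$quantile)
      rec <- reconstructPositions(triples, model)
      js <- file.path(cfg$outDir, paste0("survival_zones_", cond, ".json"))
      jsonlite::write_json(list(
        condition = cond, method = model@method, n = model@n,
        radii = as.list(model@radii),
        radii_unclamped = as.list(model@radiiUnclamped),
        clamped = as.list(model@clamped),
        center_distances = as.list(model@centerDistances),
        centers = as.data.frame(model@centers),
        extremes = as.list(model@extremes@extremes),
        fraction_outside = if (nrow(rec)) mean(rec$outside) else NA
      ), js, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, js)
      png <- file.path(cfg$outDir, paste0("survival_zones_", cond, ".png"))
      ggplot2::ggsave(png, plotSurvivalZones(model, rec),
                      width = 6, height = 5, dpi = 150)
      paths <- c(paths, png)
    }
    man <- .writeManifest(cfg, "fit_sz", attr(pops, "paths"), paths)
    invisible(c(paths, man))
  })
}

#' Run the full pipeline
#'
#' Convenience chain: simulate (when no inputs are configured), then
#' radial, distances, alleles and survival-zone stages.
#'
#' @param cfg run configuration.
#' @return all output paths, invisibly.
#' @export
cmdFull <- function(cfg) {
  paths <- character()
  if (is.null(cfg$inputResting) &&
      !file.exists(file.path(cfg$outDir, "population_resting.tsv")))
    paths <- c(paths, cmdSimulate(cfg))
  invisible(c(paths, cmdRadial(cfg), cmdDistances(cfg), cmdAlleles(cfg),
              cmdFitSZ(cfg)))
}
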