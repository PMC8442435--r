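#' @rdname FishPopulation-class
#' @param x a \linkS4class{FishPopulation}.
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))

#' @rdname FishPopulation-class
#' @export
setGeneric("nucleusTable", function(x) standardGeneric("nucleusTable"))

#' @rdname FishPopulation-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname FishPopulation-class
#' @export
setGeneric("nNuclei", function(x) standardGeneric("nNuclei"))

#' @rdname SurvivalZoneModel-class
#' @param object a fitted \linkS4class{SurvivalZoneModel}.
#' @export
setGeneric("confinementRadii", function(object) standardGeneric("confinementRadii"))

#' @rdname SurvivalZoneModel-class
#' @export
setGeneric("zoneCenters", function(object) standardGeneric("zoneCenters"))

#' @rdname SurvivalZoneModel-class
#' @export
setGeneric("zoneExtremes", function(object) standardGeneric("zoneExtremes"))

#' @rdname FishPopulation-class
#' @export
setMethod("spotTable", "FishPopulation", function(x) x@spots)

#' @rdname FishPopulation-class
#' @export
setMethod("nucleusTable", "FishPopulation", function(x) x@nuclei)

#' @rdname FishPopulation-class
#' @export
setMethod("groundTruth", "FishPopulation", function(x) x@groundTruth)

#' @rdname FishPopulation-class
#' @export
setMethod("nNuclei", "FishPopulation", function(x) nrow(x@nuclei))

#' @rdname SurvivalZoneModel-class
#' @export
setMethod("confinementRadii", "SurvivalZoneModel", function(object) object@radii)

#' @rdname SurvivalZoneModel-class
#' @export
setMethod("zoneCenters", "SurvivalZoneModel", function(object) object@centers)

#' @rdname SurvivalZoneModel-class
#' @export
setMethod("zoneExtremes", "SurvivalZoneModel", function(object) object@extremes)

#' @rdname PairwiseExtremes-class
#' @param x a \linkS4class{PairwiseExtremes}.
#' @export
setGeneric("extremeValues", function(x) standardGeneric("extremeValues"))

#' @rdname PairwiseExtremes-class
#' @export
setMethod("extremeValues", "PairwiseExtremes", function(x) x@extremes)

#' @rdname PatternCounts-class
#' @param x a \linkS4class{PatternCounts}.
#' @param ... unused.
#' @export
setMethod("as.vector", "PatternCounts", function(x, mode = "any") {
  c(CC = x@nCC, CD = x@nCD, DD = x@nDD)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d nuclei/condition, nucleus radius %.2f +/- %.2f um\n",
              object@nNuclei, object@nucleusRadiusMean, object@nucleusRadiusSd))
  cat(sprintf("  SZ radii (r,g,b): %s um; spot radius %.2f um\n",
              paste(format(object@szRadii[LOCI], digits = 3), collapse = ", "),
              object@spotRadius))
  cat(sprintf("  frac decompacted %.2f; activation: +%.2f um on %s\n",
              object@fracDecompacted, object@activationShift,
              paste(object@activationPair, collapse = "-")))
  cat(sprintf("  noise sd %.3f um; seed %d; voxel %s um\n",
              object@measurementNoiseSd, object@seed,
              paste(format(object@voxelSize), collapse = " x ")))
})

setMethod("show", "FishPopulation", function(object) {
  cat(sprintf("FishPopulation: %d nuclei, %d spots\n",
              nrow(object@nuclei), nrow(object@spots)))
  if (nrow(object@nuclei)) {
    tab <- table(object@nuclei$species, object@nuclei$condition)
    print(tab)
  }
  if (length(object@groundTruth))
    cat("  with simulation ground truth\n")
})

setMethod("show", "PairwiseExtremes", function(object) {
  cat(sprintf("PairwiseExtremes over %d triples (q = %g)\n", object@n, object@q))
  e <- object@extremes
  for (p in PAIRS)
    cat(sprintf("  %s (%s): [%.4f, %.4f]\n", p, PAIR_SIDE[p],
                e[paste0(p, "min")], e[paste0(p, "max")]))
})

setMethod("show", "SurvivalZoneModel", function(object) {
  cat(sprintf("SurvivalZoneModel (method '%s', n = %d)\n", object@method, object@n))
  for (l in LOCI)
    cat(sprintf("  R_%s (%s) = %.4f%s\n", l, LOCUS_CHANNEL[l], object@radii[l],
                if (object@clamped[l]) sprintf(" [clamped from %.4f]",
                                               object@radiiUnclamped[l]) else ""))
  cat("  centers (canonical 2D frame):\n")
  print(round(object@centers, 4))
})

setMethod("show", "PatternCounts", function(object) {
  cat(sprintf("PatternCounts [%s, %s]: C-C %d, C-D %d, D-D %d (excluded %d)\n",
              paste(unique(object@species), collapse = "/"),
              paste(unique(object@condition), collapse = "/"),
              object@nCC, object@nCD, object@nDD, object@nExcluded))
})
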