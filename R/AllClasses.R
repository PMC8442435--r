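#' @import methods
NULL

## Channel vocabulary: one fluorescent spot per MHC-like region, two alleles
## per nucleus.  Locus colour codes follow the survival-zone convention:
## r = class II, g = class I, b = class III.
CHANNELS <- c("classI", "classII", "classIII")
LOCI <- c("r", "g", "b")
LOCUS_CHANNEL <- c(r = "classII", g = "classI", b = "classIII")
## pairwise distance names in locus-colour space and their channel pairs;
## rg = classI-classII ("a"), rb = classII-classIII ("b"), gb = classI-classIII ("c")
PAIRS <- c("rg", "rb", "gb")
PAIR_CHANNELS <- list(
  rg = c("classII", "classI"),
  rb = c("classII", "classIII"),
  gb = c("classI", "classIII")
)
PAIR_SIDE <- c(rg = "a", rb = "b", gb = "c")

#' Simulation configuration for synthetic 3D-FISH nuclei
#'
#' Holds the ground-truth parameters of a simulated cell population: spherical
#' nuclei, two alleles per nucleus, three loci per allele, each locus confined
#' to a "survival zone" sphere.  All lengths are in micrometres.
#'
#' @slot nNuclei number of nuclei per condition.
#' @slot nucleusRadiusMean,nucleusRadiusSd mean and standard deviation of the
#'   nucleus radius (\eqn{\mu m}).
#' @slot szCenters list of two 3x3 matrices (rows \code{r}, \code{g},
#'   \code{b}; columns x, y, z), the survival-zone centers of each allele
#'   relative to the nucleus center (\eqn{\mu m}).
#' @slot szRadii named numeric of length 3 (\code{r}, \code{g}, \code{b}),
#'   the confinement radii (\eqn{\mu m}).
#' @slot spotRadius radius of a rendered/measured fluorescent spot
#'   (\eqn{\mu m}); the compaction threshold for a pair of spots is the sum
#'   of their radii.
#' @slot fracDecompacted probability that an allele is decompacted.
#' @slot activationPair two channel names; under the "activated" condition the
#'   distance between these two loci is lengthened by \code{activationShift}.
#' @slot activationShift extra separation (\eqn{\mu m}) applied to
#'   \code{activationPair} in activated nuclei.
#' @slot measurementNoiseSd per-coordinate Gaussian localization noise
#'   (\eqn{\mu m}).
#' @slot seed integer RNG seed (mandatory; the generator derives one
#'   sub-stream per nucleus so earlier nuclei are unchanged when more are
#'   added).
#' @slot voxelSize voxel pitch (x, y, z) in \eqn{\mu m} used when rendering
#'   image stacks.
#' @slot species species label attached to simulated records.
#' @export
setClass("SimulationConfig",
  representation(
    nNuclei = "integer",
    nucleusRadiusMean = "numeric",
    nucleusRadiusSd = "numeric",
    szCenters = "list",
    szRadii = "numeric",
    spotRadius = "numeric",
    fracDecompacted = "numeric",
    activationPair = "character",
    activationShift = "numeric",
    measurementNoiseSd = "numeric",
    seed = "integer",
    voxelSize = "numeric",
    species = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@nNuclei) != 1L || object@nNuclei < 1L)
    msg <- c(msg, "nNuclei must be a single positive integer")
  if (object@nucleusRadiusMean <= 0)
    msg <- c(msg, "nucleusRadiusMean must be > 0")
  if (object@nucleusRadiusSd < 0)
    msg <- c(msg, "nucleusRadiusSd must be >= 0")
  if (length(object@szCenters) != 2L ||
      !all(vapply(object@szCenters, function(m)
        is.matrix(m) && all(dim(m) == c(3L, 3L)), logical(1))))
    msg <- c(msg, "szCenters must be a list of two 3x3 matrices (alleles)")
  if (length(object@szRadii) != 3L || any(object@szRadii <= 0))
    msg <- c(msg, "szRadii must be three positive radii")
  if (!identical(sort(names(object@szRadii)), sort(LOCI)))
    msg <- c(msg, "szRadii must be named r, g, b")
  if (object@spotRadius <= 0)
    msg <- c(msg, "spotRadius must be > 0")
  if (object@fracDecompacted < 0 || object@fracDecompacted > 1)
    msg <- c(msg, "fracDecompacted must be in [0, 1]")
  if (length(object@activationPair) != 2L ||
      !all(object@activationPair %in% CHANNELS))
    msg <- c(msg, "activationPair must be two channel names")
  if (object@measurementNoiseSd < 0)
    msg <- c(msg, "measurementNoiseSd must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive values")
  ## every survival zone must fit inside the smallest plausible nucleus
  rmin <- object@nucleusRadiusMean - 3 * object@nucleusRadiusSd
  for (a in seq_along(object@szCenters)) {
    cen <- object@szCenters[[a]]
    for (l in seq_len(3L)) {
      reach <- sqrt(sum(cen[l, ]^2)) + object@szRadii[rownames(cen)[l] %||% l]
      if (reach > rmin)
        msg <- c(msg, sprintf(
          "survival zone '%s' of allele %d (reach %.2f um) does not fit inside the nucleus (min radius %.2f um)",
          rownames(cen)[l] %||% as.character(l), a, reach, rmin))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Population of 3D-FISH nuclei
#'
#' Container for a set of scored nuclei.  \code{nuclei} has one row per
#' nucleus (id, species, condition, center, radius); \code{spots} has one row
#' per fluorescent spot (nucleus id, channel, 3D centroid in \eqn{\mu m},
#' spot radius).  For simulated data \code{groundTruth} carries the true
#' allele assignments, allele states and noise-free locus positions.
#'
#' @slot spots data.frame of spot records.
#' @slot nuclei data.frame of nucleus records.
#' @slot groundTruth list (empty for real data).
#' @export
setClass("FishPopulation",
  representation(
    spots = "data.frame",
    nuclei = "data.frame",
    groundTruth = "list"
  )
)

setValidity("FishPopulation", function(object) {
  msg <- character()
  need_n <- c("nucleus_id", "species", "condition",
              "nucleus_cx", "nucleus_cy", "nucleus_cz", "nucleus_radius_um")
  need_s <- c("nucleus_id", "channel", "x_um", "y_um", "z_um", "spot_radius_um")
  if (!all(need_n %in% names(object@nuclei)))
    msg <- c(msg, paste("nuclei is missing columns:",
                        paste(setdiff(need_n, names(object@nuclei)), collapse = ", ")))
  if (!all(need_s %in% names(object@spots)))
    msg <- c(msg, paste("spots is missing columns:",
                        paste(setdiff(need_s, names(object@spots)), collapse = ", ")))
  if (!length(msg)) {
    if (!all(object@spots$channel %in% CHANNELS))
      msg <- c(msg, "spot channels must be classI, classII or classIII")
    if (nrow(object@spots) && !all(object@spots$nucleus_id %in% object@nuclei$nucleus_id))
      msg <- c(msg, "spots refer to unknown nucleus ids")
    if (any(object@spots$spot_radius_um <= 0))
      msg <- c(msg, "spot radii must be > 0")
    cnt <- table(object@spots$nucleus_id, object@spots$channel)
    if (length(cnt) && any(cnt > 2L))
      msg <- c(msg, "a nucleus has more than 2 spots in one channel")
  }
  if (length(msg)) msg else TRUE
})

#' Pairwise distance extremes over a cell population
#'
#' The minimum and maximum of each of the three inter-locus distances
#' (\code{rg}, \code{rb}, \code{gb}) over all scored cells (and alleles).
#' These are the sufficient statistics of the survival-zone closed form.
#'
#' @slot extremes named numeric of length 6: \code{rgmin}, \code{rgmax},
#'   \code{rbmin}, \code{rbmax}, \code{gbmin}, \code{gbmax}.
#' @slot n number of distance triples used.
#' @slot q trimming quantile (0 = strict min/max).
#' @export
setClass("PairwiseExtremes",
  representation(extremes = "numeric", n = "integer", q = "numeric")
)

setValidity("PairwiseExtremes", function(object) {
  msg <- character()
  need <- c("rgmin", "rgmax", "rbmin", "rbmax", "gbmin", "gbmax")
  if (!identical(names(object@extremes), need))
    msg <- c(msg, paste("extremes must be named", paste(need, collapse = ", ")))
  else {
    e <- object@extremes
    if (any(e < 0)) msg <- c(msg, "distances must be non-negative")
    for (p in PAIRS)
      if (e[paste0(p, "min")] > e[paste0(p, "max")])
        msg <- c(msg, sprintf("%smin exceeds %smax", p, p))
  }
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@q < 0 || object@q >= 0.5) msg <- c(msg, "q must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Fitted survival-zone model
#'
#' Per-locus confinement ("survival zone") radii, the 2D layout of the zone
#' centers in a canonical frame (locus \code{r} at the origin, \code{g} on
#' the positive x-axis, \code{b} in the upper half-plane), and the pairwise
#' distance extremes the fit was derived from.
#'
#' @slot radii named numeric (\code{r}, \code{g}, \code{b}); clamped at 0.
#' @slot radiiUnclamped the raw closed-form / fitted values before clamping.
#' @slot clamped logical flags per locus.
#' @slot centers 3x2 matrix of zone centers (rows \code{r}, \code{g},
#'   \code{b}).
#' @slot centerDistances named numeric (\code{rg}, \code{rb}, \code{gb}).
#' @slot extremes the \linkS4class{PairwiseExtremes} observed in the data.
#' @slot method "extremes" (paper closed form) or "mle" (sphere-model
#'   maximum likelihood refinement).
#' @slot n number of distance triples used.
#' @export
setClass("SurvivalZoneModel",
  representation(
    radii = "numeric",
    radiiUnclamped = "numeric",
    clamped = "logical",
    centers = "matrix",
    centerDistances = "numeric",
    extremes = "PairwiseExtremes",
    method = "character",
    n = "integer"
  )
)

setValidity("SurvivalZoneModel", function(object) {
  msg <- character()
  if (!identical(names(object@radii), LOCI))
    msg <- c(msg, "radii must be named r, g, b")
  if (any(object@radii < 0)) msg <- c(msg, "clamped radii must be >= 0")
  if (!all(dim(object@centers) == c(3L, 2L)))
    msg <- c(msg, "centers must be a 3x2 matrix")
  if (!identical(names(object@centerDistances), PAIRS))
    msg <- c(msg, "centerDistances must be named rg, rb, gb")
  else if (all(dim(object@centers) == c(3L, 2L))) {
    ## the 2D layout must reproduce the stored center distances
    cd <- object@centerDistances
    lay <- c(
      rg = sqrt(sum((object@centers[1, ] - object@centers[2, ])^2)),
      rb = sqrt(sum((object@centers[1, ] - object@centers[3, ])^2)),
      gb = sqrt(sum((object@centers[2, ] - object@centers[3, ])^2))
    )
    if (any(abs(lay - cd) > 1e-6 * pmax(1, cd)))
      msg <- c(msg, "center layout is inconsistent with centerDistances")
  }
  if (length(msg)) msg else TRUE
})

#' Nucleus compaction-pattern counts
#'
#' Counts of nuclei whose two alleles are both compacted (C-C), mixed (C-D)
#' or both decompacted (D-D), plus nuclei excluded because an allele was
#' ambiguous or the spots could not be paired.
#'
#' @slot nCC,nCD,nDD,nExcluded non-negative integer counts.
#' @slot condition,species labels of the population counted.
#' @export
setClass("PatternCounts",
  representation(
    nCC = "integer", nCD = "integer", nDD = "integer", nExcluded = "integer",
    condition = "character", species = "character"
  )
)

setValidity("PatternCounts", function(object) {
  if (any(c(object@nCC, object@nCD, object@nDD, object@nExcluded) < 0L))
    "counts must be non-negative" else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
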