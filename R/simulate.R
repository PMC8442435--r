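#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{SimulationConfig}.  Defaults emulate a
#' typical 3D-FISH experiment on macrophage-like nuclei: 60--88 nuclei scored
#' per condition (default 75), near-spherical nuclei of radius about 5
#' \eqn{\mu m}, three loci per allele confined in survival-zone spheres well
#' inside the nucleus, BAC-probe spots of radius 0.25 \eqn{\mu m}, and
#' confocal-like anisotropic voxels of 0.079 x 0.079 x 0.244 \eqn{\mu m}.
#'
#' @param nNuclei nuclei per condition.
#' @param nucleusRadiusMean,nucleusRadiusSd nucleus radius distribution
#'   (\eqn{\mu m}).
#' @param szCenters either a 3x3 matrix (rows \code{r}, \code{g}, \code{b})
#'   of survival-zone centers for allele 1, in which case allele 2 uses the
#'   point reflection through the nucleus center, or a list of two such
#'   matrices.
#' @param szRadii named confinement radii (\code{r}, \code{g}, \code{b}),
#'   \eqn{\mu m}.
#' @param spotRadius fluorescent spot radius (\eqn{\mu m}).
#' @param fracDecompacted probability an allele is decompacted.
#' @param activationPair channel pair whose separation is lengthened upon
#'   activation.
#' @param activationShift extra separation (\eqn{\mu m}) for that pair in
#'   activated nuclei.
#' @param measurementNoiseSd per-coordinate localization noise (\eqn{\mu m}).
#' @param seed mandatory integer RNG seed.
#' @param voxelSize rendering voxel pitch (x, y, z) in \eqn{\mu m}.
#' @param species species label for the simulated records.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @export
simulationConfig <- function(nNuclei = 75L,
                             nucleusRadiusMean = 5,
                             nucleusRadiusSd = 0.25,
                             szCenters = NULL,
                             szRadii = c(r = 0.8, g = 0.6, b = 1.0),
                             spotRadius = 0.25,
                             fracDecompacted = 0.5,
                             activationPair = c("classI", "classIII"),
                             activationShift = 0.6,
                             measurementNoiseSd = 0.05,
                             seed = NULL,
                             voxelSize = c(0.079, 0.079, 0.244),
                             species = "pig") {
  if (is.null(seed))
    stop("a seed is mandatory: every simulation must be reproducible")
  if (is.null(szCenters)) {
    szCenters <- rbind(
      r = c(1.2, 1.2, 0.5),
      g = c(2.8, 1.2, 0.5),
      b = c(1.8, 2.4, 0.4)
    )
  }
  if (is.matrix(szCenters))
    szCenters <- list(szCenters, -szCenters)
  szCenters <- lapply(szCenters, function(m) {
    m <- as.matrix(m)
    if (is.null(rownames(m))) rownames(m) <- LOCI
    m[LOCI, , drop = FALSE]
  })
  szRadii <- szRadii[LOCI]
  new("SimulationConfig",
      nNuclei = as.integer(nNuclei),
      nucleusRadiusMean = nucleusRadiusMean,
      nucleusRadiusSd = nucleusRadiusSd,
      szCenters = szCenters,
      szRadii = szRadii,
      spotRadius = spotRadius,
      fracDecompacted = fracDecompacted,
      activationPair = activationPair,
      activationShift = activationShift,
      measurementNoiseSd = measurementNoiseSd,
      seed = as.integer(seed),
      voxelSize = voxelSize,
      species = species)
}

#' Uniform points in a sphere
#'
#' @param n number of points.
#' @param radius sphere radius.
#' @param center length-3 center.
#' @return an n x 3 matrix.
#' @examples
#' p <- runifSphere(100, 1)
#' max(sqrt(rowSums(p^2))) <= 1
#' @export
runifSphere <- function(n, radius = 1, center = c(0, 0, 0)) {
  if (radius < 0) stop("radius must be >= 0")
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  v <- v / nrm
  p <- v * (radius * stats::runif(n)^(1 / 3))
  sweep(p, 2, center, "+")
}

## deterministic per-nucleus sub-stream: adding nuclei or switching condition
## never perturbs earlier draws.  Offsets stay far below .Machine$integer.max.
.nucleusSeed <- function(seed, condition, i) {
  offset <- if (condition == "activated") 500000L else 0L
  (as.integer(seed) + offset + as.integer(i)) %% 2147483647L
}

#' Simulate a 3D-FISH cell population with known ground truth
#'
#' Draws \code{nNuclei} spherical nuclei.  Each nucleus carries two alleles;
#' each allele has one locus per channel, sampled uniformly inside its
#' survival-zone sphere.  Allele compaction states are Bernoulli draws with
#' probability \code{fracDecompacted} of being decompacted; the compaction is
#' imposed geometrically by scaling the locus triplet about its centroid until
#' all pairwise distances are on the intended side of the classification
#' threshold (the sum of the two spot radii), so ground-truth labels are
#' unambiguous.  In the \code{"activated"} condition the two loci of
#' \code{activationPair} are pushed apart by \code{activationShift} by
#' rotating them about the third locus, which lengthens that one pairwise
#' distance while leaving the other two distances of the allele exactly
#' unchanged.  Gaussian localization noise is added last, and spots are
#' kept inside the nucleus.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param condition \code{"resting"} or \code{"activated"}.
#' @return a \linkS4class{FishPopulation} whose \code{groundTruth} holds the
#'   per-allele true states and noise-free locus positions.
#' @examples
#' pop <- simulatePopulation(simulationConfig(nNuclei = 5, seed = 1))
#' nNuclei(pop)
#' @export
simulatePopulation <- function(config, condition = c("resting", "activated")) {
  condition <- match.arg(condition)
  validObject(config)
  n <- config@nNuclei
  thr <- 2 * config@spotRadius

  ## smallest nucleus radius that contains every survival zone
  reach <- max(vapply(seq_len(2), function(a) {
    cen <- config@szCenters[[a]]
    max(sqrt(rowSums(cen^2)) + config@szRadii[LOCI])
  }, numeric(1)))

  nucleus <- vector("list", n)
  spotrec <- vector("list", n)
  truth <- vector("list", n)
  truepos <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(.nucleusSeed(config@seed, condition, i))
    R <- max(stats::rnorm(1, config@nucleusRadiusMean, config@nucleusRadiusSd),
             reach + 0.1)
    states <- ifelse(stats::runif(2) < config@fracDecompacted, "D", "C")

    sp <- matrix(NA_real_, 6, 3)
    chan <- character(6)
    allele <- integer(6)
    true_states <- character(2)
    for (a in 1:2) {
      cen <- config@szCenters[[a]]
      pos <- t(vapply(LOCI, function(l)
        drop(runifSphere(1, config@szRadii[l], cen[l, ])), numeric(3)))
      pos <- .imposeCompaction(pos, states[a], thr, R)
      idx <- (a - 1) * 3 + 1:3
      sp[idx, ] <- pos
      chan[idx] <- LOCUS_CHANNEL[LOCI]
      allele[idx] <- a
      true_states[a] <- states[a]
    }

    if (condition == "activated" && config@activationShift > 0) {
      for (a in 1:2) {
        idx <- which(allele == a)
        i1 <- idx[chan[idx] == config@activationPair[1]]
        i2 <- idx[chan[idx] == config@activationPair[2]]
        ip <- idx[!(chan[idx] %in% config@activationPair)]
        sp[c(i1, i2), ] <- .openPair(sp[i1, ], sp[i2, ], sp[ip, ],
                                     config@activationShift)
      }
    }

    true_pos <- sp
    if (config@measurementNoiseSd > 0)
      sp <- sp + matrix(stats::rnorm(18, 0, config@measurementNoiseSd), 6, 3)
    ## keep spots inside the nucleus envelope
    d <- sqrt(rowSums(sp^2))
    out <- d > R
    if (any(out))
      sp[out, ] <- sp[out, , drop = FALSE] * (0.999 * R / d[out])

    id <- sprintf("%s_%s_%04d", config@species, condition, i)
    nucleus[[i]] <- data.frame(
      nucleus_id = id, species = config@species, condition = condition,
      nucleus_cx = 0, nucleus_cy = 0, nucleus_cz = 0, nucleus_radius_um = R,
      stringsAsFactors = FALSE)
    spotrec[[i]] <- data.frame(
      nucleus_id = id, condition = condition, species = config@species,
      allele_truth = allele, channel = chan,
      x_um = sp[, 1], y_um = sp[, 2], z_um = sp[, 3],
      spot_radius_um = config@spotRadius,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      nucleus_id = id, allele = 1:2, state = true_states,
      stringsAsFactors = FALSE)
    truepos[[i]] <- data.frame(
      nucleus_id = id, allele = allele, channel = chan,
      x_um = true_pos[, 1], y_um = true_pos[, 2], z_um = true_pos[, 3],
      stringsAsFactors = FALSE)
  }

  gt <- list(
    alleleStates = do.call(rbind, truth),
    truePositions = do.call(rbind, truepos),
    condition = condition,
    szRadii = config@szRadii,
    szCenters = config@szCenters,
    seed = config@seed
  )
  new("FishPopulation",
      spots = do.call(rbind, spotrec),
      nuclei = do.call(rbind, nucleus),
      groundTruth = gt)
}

## Lengthen the p1-p2 distance by `shift` while keeping |p1 - pivot| and
## |p2 - pivot| fixed: rotate both loci about the pivot within their common
## plane (opening the angle at the pivot).  The other two pairwise distances
## of the triplet are therefore exactly unchanged.  The opening saturates at
## the collinear configuration.
.openPair <- function(p1, p2, pivot, shift) {
  u1 <- p1 - pivot; u2 <- p2 - pivot
  l1 <- sqrt(sum(u1^2)); l2 <- sqrt(sum(u2^2))
  if (l1 == 0 || l2 == 0) return(rbind(p1, p2))
  d_old <- sqrt(sum((p1 - p2)^2))
  d_new <- d_old + shift
  cosphi <- (l1^2 + l2^2 - d_new^2) / (2 * l1 * l2)
  cosphi <- min(max(cosphi, -1), 1)
  phi_old <- acos(min(max(sum(u1 * u2) / (l1 * l2), -1), 1))
  dphi <- acos(cosphi) - phi_old
  ## in-plane orthonormal frame (e1 along u1)
  e1 <- u1 / l1
  w <- u2 - sum(u2 * e1) * e1
  if (sqrt(sum(w^2)) < 1e-12) {
    ## parallel rays: pick any perpendicular direction
    w <- c(-e1[2], e1[1], 0)
    if (sqrt(sum(w^2)) < 1e-12) w <- c(0, -e1[3], e1[2])
  }
  e2 <- w / sqrt(sum(w^2))
  rot <- function(v, ang) {
    x <- sum(v * e1); y <- sum(v * e2)
    rem <- v - x * e1 - y * e2
    (x * cos(ang) - y * sin(ang)) * e1 +
      (x * sin(ang) + y * cos(ang)) * e2 + rem
  }
  ## open symmetrically: u1 by -dphi/2, u2 by +dphi/2 (angles measured in
  ## the e1,e2 plane where u2 has positive y)
  rbind(pivot + rot(u1, -dphi / 2), pivot + rot(u2, dphi / 2))
}

## Scale a 3-locus triplet about its centroid so that all pairwise distances
## fall on the intended side of the threshold; cap the expansion so loci stay
## inside the nucleus.
.imposeCompaction <- function(pos, state, thr, R) {
  d <- stats::dist(pos)
  ctr <- colMeans(pos)
  if (state == "C") {
    if (max(d) >= thr * 0.8) {
      s <- (thr * 0.8) / max(d)
      pos <- sweep(sweep(pos, 2, ctr) * s, 2, ctr, "+")
    }
  } else {
    if (min(d) < thr * 1.25) {
      s <- (thr * 1.25) / min(d)
      ## expansion limit: keep all loci inside the nucleus
      rad <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
      smax <- if (max(rad) > 0)
        (R - sqrt(sum(ctr^2))) / max(rad) else s
      s <- min(s, max(smax, 1))
      pos <- sweep(sweep(pos, 2, ctr) * s, 2, ctr, "+")
    }
  }
  pos
}

#' Assemble a FishPopulation from tables
#'
#' @param spots data.frame of spot records (see
#'   \linkS4class{FishPopulation}).
#' @param nuclei data.frame of nucleus records.
#' @param groundTruth optional list of simulation ground truth.
#' @return a validated \linkS4class{FishPopulation}.
#' @export
fishPopulation <- function(spots, nuclei, groundTruth = list()) {
  new("FishPopulation", spots = spots, nuclei = nuclei,
      groundTruth = groundTruth)
}
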