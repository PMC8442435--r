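#' Normalized radial position of a spot
#'
#' Distance from the spot centroid to the nucleus center divided by the
#' nucleus local radius.  For the default spherical envelope the local
#' radius is the nucleus radius; with \code{semiaxes} the envelope is an
#' axis-aligned ellipsoid and the local radius is the envelope distance
#' along the center-to-spot ray.  0 is the nucleus center, 1 the periphery.
#' Values slightly above 1 (within \code{tol}) are clipped to 1 with a
#' warning; larger excursions are an error.
#'
#' @param position spot centroid, length-3 or n x 3 matrix (\eqn{\mu m}).
#' @param center nucleus center (\eqn{\mu m}).
#' @param radius nucleus radius (\eqn{\mu m}); with \code{semiaxes} given,
#'   the envelope semi-axis lengths are \code{radius * semiaxes}.
#' @param tol tolerance for spots marginally outside the envelope.
#' @param semiaxes optional length-3 relative semi-axes of an ellipsoidal
#'   envelope (e.g. \code{c(1, 1, 0.7)} for a flattened nucleus).
#' @return radial position(s) in [0, 1].
#' @export
radialPosition <- function(position, center, radius, tol = 0.05,
                           semiaxes = NULL) {
  if (radius <= 0) stop("nucleus radius must be > 0")
  if (!is.matrix(position)) position <- matrix(position, ncol = 3)
  rel <- sweep(position, 2, center)
  if (is.null(semiaxes)) {
    d <- sqrt(rowSums(rel^2)) / radius
  } else {
    if (length(semiaxes) != 3 || any(semiaxes <= 0))
      stop("semiaxes must be three positive values")
    ## local radius along the ray: |u| / |u/axes| for unit ray direction,
    ## so the normalized position is |rel scaled by the axes|
    d <- sqrt(rowSums(sweep(rel, 2, radius * semiaxes, "/")^2))
  }
  if (any(d > 1 + tol))
    stop(sprintf("spot at radial position %.3f lies outside the nucleus envelope (tol %.3f)",
                 max(d), tol))
  if (any(d > 1)) {
    warning(sprintf("%d radial position(s) clipped to 1", sum(d > 1)))
    d <- pmin(d, 1)
  }
  d
}

#' Normalized pairwise spot distance
#'
#' Euclidean 3D center-to-center distance divided by the nucleus diameter
#' (2 x equivalent-sphere radius), making cells of different sizes
#' comparable.
#'
#' @param p1,p2 spot centroids (\eqn{\mu m}), length-3 or n x 3 matrices.
#' @param radius nucleus radius (\eqn{\mu m}).
#' @return dimensionless distance(s).
#' @export
normalizedPairDistance <- function(p1, p2, radius) {
  if (any(radius <= 0)) stop("nucleus radius must be > 0 (zero diameter)")
  if (!is.matrix(p1)) p1 <- matrix(p1, ncol = 3)
  if (!is.matrix(p2)) p2 <- matrix(p2, ncol = 3)
  sqrt(rowSums((p1 - p2)^2)) / (2 * radius)
}

#' Internal angles of the three-locus triangle
#'
#' Given the three pairwise distances \code{a} (class I-class II), \code{b}
#' (class II-class III) and \code{c} (class I-class III), returns the
#' internal angles in degrees, labeled by vertex: \code{A} at the class III
#' vertex (opposite side \code{a}), \code{B} at the class I vertex (opposite
#' \code{b}), \code{C} at the class II vertex (opposite \code{c}).  Angles
#' are computed by the law of cosines and always sum to 180 degrees.
#'
#' Degenerate inputs are resolved by continuity: a collinear triangle (one
#' side equal to the sum of the others) yields 180 at the vertex opposite
#' the long side and 0 at the other two; a zero-length side yields 0 at the
#' vertex opposite it and 90 at each of its endpoints (the limit of an
#' isoceles triangle as that side shrinks); the all-zero triangle returns
#' (60, 60, 60) by scale invariance.
#'
#' @param a,b,c pairwise distances (any common unit; angles are invariant to
#'   joint scaling).
#' @param tol relative tolerance for triangle-inequality violations.
#' @return named numeric: angles \code{A}, \code{B}, \code{C} in degrees.
#' @examples
#' internalAngles(1, 1, 1)
#' internalAngles(5, 4, 3)  # right angle opposite the 5 side
#' @export
internalAngles <- function(a, b, c, tol = 1e-6) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  sides <- c(a = a, b = b, c = c)
  if (any(sides < 0)) stop("distances must be non-negative")
  s <- max(sides)
  if (s == 0) return(c(A = 60, B = 60, C = 60))
  excess <- 2 * s - sum(sides)
  if (excess > tol * s)
    stop(sprintf(
      "triangle inequality violated: a = %g, b = %g, c = %g", a, b, c))
  zero <- sides <= tol * s
  if (any(zero)) {
    ## continuity limit: 0 opposite the vanishing side, 90 at its endpoints
    ang <- c(A = 90, B = 90, C = 90)
    ang[which(zero)[1]] <- 0
    return(ang)
  }
  cosA <- (b^2 + c^2 - a^2) / (2 * b * c)
  cosB <- (a^2 + c^2 - b^2) / (2 * a * c)
  cosC <- (a^2 + b^2 - c^2) / (2 * a * b)
  ang <- acos(pmin(pmax(c(A = cosA, B = cosB, C = cosC), -1), 1)) * 180 / pi
  ## enforce the exact 180-degree sum against rounding
  ang * (180 / sum(ang))
}

#' Per-allele triangle metrics and radial positions
#'
#' Computes, for each allele of each nucleus that passes spot pairing, the
#' normalized pairwise distances \code{a} (I-II), \code{b} (II-III),
#' \code{c} (I-III), the internal angles \code{A}, \code{B}, \code{C}
#' (degrees; see [internalAngles()]) and the normalized radial position of
#' each spot.
#'
#' @param pop a \linkS4class{FishPopulation}.
#' @param separabilityMargin relative score margin for [pairSpots()].
#' @param pooled if \code{TRUE}, also return per-nucleus means over the two
#'   alleles in attribute \code{"pooled"}.
#' @return a data.frame with one row per allele; nuclei that fail pairing
#'   are skipped (their ids are in attribute \code{"excluded"}).
#' @export
triangleMetrics <- function(pop, separabilityMargin = 0.2, pooled = FALSE) {
  nuc <- pop@nuclei
  res <- vector("list", nrow(nuc))
  excluded <- character()
  for (i in seq_len(nrow(nuc))) {
    id <- nuc$nucleus_id[i]
    sp <- pop@spots[pop@spots$nucleus_id == id, ]
    pr <- pairSpots(sp, separabilityMargin = separabilityMargin)
    if (!pr$ok) {
      excluded <- c(excluded, id)
      next
    }
    R <- nuc$nucleus_radius_um[i]
    ctr <- c(nuc$nucleus_cx[i], nuc$nucleus_cy[i], nuc$nucleus_cz[i])
    rows <- lapply(1:2, function(a) {
      al <- pr$alleles[[a]]
      pos <- al$positions
      dn <- normalizedPairDistance(
        pos[c("classI", "classII", "classI"), , drop = FALSE],
        pos[c("classII", "classIII", "classIII"), , drop = FALSE], R)
      names(dn) <- c("a", "b", "c")
      ang <- internalAngles(dn["a"], dn["b"], dn["c"])
      rad <- radialPosition(pos, ctr, R)
      data.frame(
        nucleus_id = id, species = nuc$species[i],
        condition = nuc$condition[i], allele_id = a,
        a = unname(dn["a"]), b = unname(dn["b"]), c = unname(dn["c"]),
        A = unname(ang["A"]), B = unname(ang["B"]), C = unname(ang["C"]),
        radial_classI = unname(rad[rownames(pos) == "classI"]),
        radial_classII = unname(rad[rownames(pos) == "classII"]),
        radial_classIII = unname(rad[rownames(pos) == "classIII"]),
        stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  attr(out, "excluded") <- excluded
  if (pooled && nrow(out)) {
    num <- c("a", "b", "c", "A", "B", "C",
             "radial_classI", "radial_classII", "radial_classIII")
    agg <- stats::aggregate(out[num], by = out["nucleus_id"], FUN = mean)
    attr(out, "pooled") <- agg
  }
  out
}
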