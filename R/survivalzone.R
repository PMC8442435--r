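## -------------------------------------------------------------------------
## Survival-zone inference: each locus (r = class II, g = class I,
## b = class III) is confined to a sphere; over many fixed cells the min and
## max of each pairwise inter-locus distance approach c_ij -/+ (R_i + R_j),
## where c_ij is the distance between zone centers.  Solving the three
## pairwise-sum equations gives the closed-form radii; the zone center
## layout follows by trilateration.
## -------------------------------------------------------------------------

#' Per-allele distance triples of a population
#'
#' Pairs the spots of each nucleus and returns one row per allele with the
#' three inter-locus distances in survival-zone order: \code{rg}
#' (class I-class II), \code{rb} (class II-class III), \code{gb}
#' (class I-class III), normalized by the nucleus diameter by default.
#'
#' @param pop a \linkS4class{FishPopulation}.
#' @param normalize divide by the nucleus diameter (default) or keep
#'   \eqn{\mu m}.
#' @param separabilityMargin relative margin for [pairSpots()].
#' @param allele \code{NULL} (default: pool both alleles, one row each) or
#'   1 or 2 to keep only the first- or second-scoring allele per nucleus.
#' @return matrix with columns \code{rg}, \code{rb}, \code{gb}.
#' @export
alleleDistanceTriples <- function(pop, normalize = TRUE,
                                  separabilityMargin = 0.2,
                                  allele = NULL) {
  nuc <- pop@nuclei
  keep <- if (is.null(allele)) 1:2 else as.integer(allele)
  out <- vector("list", nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    sp <- pop@spots[pop@spots$nucleus_id == nuc$nucleus_id[i], ]
    pr <- pairSpots(sp, separabilityMargin = separabilityMargin)
    if (!pr$ok) next
    out[[i]] <- t(vapply(pr$alleles[keep], function(al) {
      d <- al$distances
      c(rg = unname(d["d_I_II"]), rb = unname(d["d_II_III"]),
        gb = unname(d["d_I_III"])) /
        if (normalize) 2 * nuc$nucleus_radius_um[i] else 1
    }, numeric(3)))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Pairwise distance extremes
#'
#' Minimum and maximum of each pairwise distance over all triples.  With
#' \code{q = 0} (default) these are the strict min/max; \code{q > 0}
#' substitutes the (q, 1-q) empirical quantiles as a robustness option
#' against gross outliers.
#'
#' @param triples matrix or data.frame with columns \code{rg}, \code{rb},
#'   \code{gb} (one row per cell or allele).
#' @param q trimming quantile in [0, 0.5).
#' @return a \linkS4class{PairwiseExtremes}.
#' @export
pairwiseExtremes <- function(triples, q = 0) {
  triples <- as.matrix(triples)
  if (nrow(triples) < 2L) stop("need at least 2 distance triples")
  if (q < 0 || q >= 0.5) stop("q must be in [0, 0.5)")
  if (!all(PAIRS %in% colnames(triples)))
    stop("triples must have columns rg, rb, gb")
  e <- numeric(0)
  for (p in PAIRS) {
    x <- triples[, p]
    if (q == 0) bounds <- range(x)
    else bounds <- stats::quantile(x, c(q, 1 - q), names = FALSE)
    e[paste0(p, "min")] <- bounds[1]
    e[paste0(p, "max")] <- bounds[2]
  }
  new("PairwiseExtremes", extremes = e[c("rgmin", "rgmax", "rbmin",
                                         "rbmax", "gbmin", "gbmax")],
      n = nrow(triples), q = q)
}

#' Survival-zone radii from pairwise extremes (closed form)
#'
#' The three confinement radii solve the pairwise-sum equations
#' \eqn{R_i + R_j = (d_{ij}^{max} - d_{ij}^{min})/2}:
#' \deqn{R_g = (d_{rg}^{max} + d_{gb}^{max} + d_{rb}^{min} - d_{rb}^{max} -
#'   d_{rg}^{min} - d_{gb}^{min}) / 4}
#' and cyclically for \eqn{R_b} and \eqn{R_r}.  Noise can make a value
#' negative; negative radii are clamped to 0 with a warning, and the raw
#' values kept in attribute \code{"unclamped"}.
#'
#' @param ext a \linkS4class{PairwiseExtremes} or a named numeric of the six
#'   extremes.
#' @return named radii \code{r}, \code{g}, \code{b} (clamped at 0), with
#'   attributes \code{"unclamped"} and \code{"clamped"}.
#' @export
szRadii <- function(ext) {
  e <- if (is(ext, "PairwiseExtremes")) ext@extremes else ext
  Rg <- (e["rgmax"] + e["gbmax"] + e["rbmin"] -
         e["rbmax"] - e["rgmin"] - e["gbmin"]) / 4
  Rb <- (e["rbmax"] + e["gbmax"] + e["rgmin"] -
         e["rgmax"] - e["rbmin"] - e["gbmin"]) / 4
  Rr <- (e["rgmax"] + e["rbmax"] + e["gbmin"] -
         e["gbmax"] - e["rgmin"] - e["rbmin"]) / 4
  raw <- c(r = unname(Rr), g = unname(Rg), b = unname(Rb))
  clamped <- raw < 0
  if (any(clamped))
    warning("negative survival-zone radius clamped to 0 for locus: ",
            paste(names(raw)[clamped], collapse = ", "),
            " (noise can violate the sphere model)")
  out <- pmax(raw, 0)
  attr(out, "unclamped") <- raw
  attr(out, "clamped") <- clamped
  out
}

#' Survival-zone center layout by trilateration
#'
#' Center-to-center distances follow from the sphere model as
#' \eqn{c_{ij} = (d_{ij}^{max} + d_{ij}^{min})/2}.  The three centers are
#' placed in a canonical 2D frame: \code{r} at the origin, \code{g} on the
#' positive x-axis at \eqn{c_{rg}}, and \code{b} in the upper half-plane by
#' trilateration from \eqn{c_{rb}} and \eqn{c_{gb}}.
#'
#' @param ext a \linkS4class{PairwiseExtremes}, or a named numeric of center
#'   distances \code{rg}, \code{rb}, \code{gb}.
#' @param tol relative tolerance for triangle-inequality violations among
#'   the center distances.
#' @return 3x2 matrix of centers (rows \code{r}, \code{g}, \code{b}).
#' @export
szCenters <- function(ext, tol = 1e-6) {
  cd <- if (is(ext, "PairwiseExtremes")) {
    e <- ext@extremes
    c(rg = unname((e["rgmax"] + e["rgmin"]) / 2),
      rb = unname((e["rbmax"] + e["rbmin"]) / 2),
      gb = unname((e["gbmax"] + e["gbmin"]) / 2))
  } else ext[PAIRS]
  s <- max(cd)
  if (2 * s - sum(cd) > tol * s)
    stop(sprintf(
      "center distances violate the triangle inequality: c_rg = %g, c_rb = %g, c_gb = %g",
      cd["rg"], cd["rb"], cd["gb"]))
  x_b <- (cd["rg"]^2 + cd["rb"]^2 - cd["gb"]^2) / (2 * cd["rg"])
  y_b <- sqrt(max(cd["rb"]^2 - x_b^2, 0))
  m <- rbind(r = c(0, 0), g = c(unname(cd["rg"]), 0),
             b = c(unname(x_b), unname(y_b)))
  colnames(m) <- c("x", "y")
  m
}

## ---- uniform-sphere pair-distance distribution (exact) -------------------
## W = V2 - V1 (uniform in spheres R1, R2) has radially symmetric density
## proportional to the sphere-intersection volume; the distance to a point c
## away integrates the spherical-cap fraction over |W|.

.sphereIntersectionVolume <- function(rho, R1, R2) {
  lo <- abs(R1 - R2)
  out <- numeric(length(rho))
  out[rho <= lo] <- 4 / 3 * pi * min(R1, R2)^3
  lens <- rho > lo & rho < R1 + R2
  r <- rho[lens]
  out[lens] <- pi * (R1 + R2 - r)^2 *
    (r^2 + 2 * r * R2 - 3 * R2^2 + 2 * r * R1 + 6 * R1 * R2 - 3 * R1^2) /
    (12 * r)
  out
}

## CDF of |c zhat + V2 - V1| at points t, by fixed quadrature over |W|
.pairDistanceCdf <- function(t, c_, R1, R2, nq = 400L) {
  R1 <- max(R1, 1e-6); R2 <- max(R2, 1e-6)
  rho <- seq(1e-9, R1 + R2, length.out = nq)
  w <- rho^2 * .sphereIntersectionVolume(rho, R1, R2)
  w <- w / sum(w)
  FR <- outer(rho, t, function(r, tt)
    pmin(pmax((tt^2 - (c_ - r)^2) / (4 * c_ * r), 0), 1))
  as.vector(w %*% FR)
}

## binned negative log-likelihood of one pair's distance sample; the bin
## counts are precomputed once per fit
.binCounts <- function(x, edges) {
  nb <- length(edges) - 1L
  graphics::hist(x, breaks = c(-Inf, edges[-c(1, nb + 1)], Inf),
                 plot = FALSE)$counts
}

.pairBinnedNll <- function(cnt, edges, c_, R1, R2) {
  nb <- length(edges) - 1L
  Fe <- .pairDistanceCdf(edges[-c(1, nb + 1)], c_, R1, R2)
  p <- pmax(diff(c(0, Fe, 1)), 1e-12)
  -sum(cnt * log(p))
}

## bin edges: quantile bins in the bulk, fine linear bins in the 2% tails
## (the support endpoints carry most of the information on the radii)
.tailResolvedEdges <- function(x) {
  qs <- stats::quantile(x, seq(0.02, 0.98, length.out = 70), names = FALSE)
  lo <- min(x); hi <- max(x); pad <- (hi - lo) * 0.01
  sort(unique(c(seq(lo - pad, qs[1], length.out = 25), qs,
                seq(qs[length(qs)], hi + pad, length.out = 25))))
}

#' Fit the survival-zone model
#'
#' Estimates the three confinement radii and zone-center layout from the
#' per-allele distance triples of a population (or a raw triple matrix).
#'
#' \code{method = "extremes"} applies the closed form to the strict (or
#' q-trimmed) pairwise extremes.  \code{method = "mle"} (default) refines
#' that estimate by maximum likelihood under the same uniform-sphere model,
#' using the exact distribution of the distance between two uniform draws
#' from spheres; the likelihood is binned with tail-resolved bins and
#' maximized by Nelder-Mead from the closed-form start.  Sample extremes of
#' a bounded distribution converge only at rate \eqn{n^{-1/4}} here, so the
#' closed form on strict extremes systematically underestimates the radii
#' at realistic cell counts; the likelihood uses the whole sample and
#' converges at \eqn{n^{-1/2}}.
#'
#' @param x a \linkS4class{FishPopulation} or a matrix of distance triples
#'   (columns \code{rg}, \code{rb}, \code{gb}).
#' @param method \code{"mle"} or \code{"extremes"}.
#' @param q trimming quantile passed to [pairwiseExtremes()].
#' @param normalize when \code{x} is a population, normalize distances by
#'   the nucleus diameter (default TRUE).
#' @param separabilityMargin relative margin for [pairSpots()].
#' @param allele \code{NULL} (pool both alleles, the default) or 1 or 2 for
#'   per-allele fitting when \code{x} is a population.
#' @return a \linkS4class{SurvivalZoneModel}.
#' @export
fitSurvivalZones <- function(x, method = c("mle", "extremes"), q = 0,
                             normalize = TRUE, separabilityMargin = 0.2,
                             allele = NULL) {
  method <- match.arg(method)
  triples <- if (is(x, "FishPopulation"))
    alleleDistanceTriples(x, normalize = normalize,
                          separabilityMargin = separabilityMargin,
                          allele = allele)
  else as.matrix(x)
  ext <- pairwiseExtremes(triples, q = q)
  rad0 <- suppressWarnings(szRadii(ext))
  e <- ext@extremes
  cd0 <- c(rg = unname((e["rgmax"] + e["rgmin"]) / 2),
           rb = unname((e["rbmax"] + e["rbmin"]) / 2),
           gb = unname((e["gbmax"] + e["gbmin"]) / 2))

  if (method == "extremes") {
    raw <- attr(rad0, "unclamped")
    radii <- stats::setNames(as.numeric(rad0), LOCI)
  } else {
    d <- list(rg = triples[, "rg"], rb = triples[, "rb"], gb = triples[, "gb"])
    ed <- lapply(d, .tailResolvedEdges)
    cn <- mapply(.binCounts, d, ed, SIMPLIFY = FALSE)
    nll <- function(par) {
      if (any(par[1:3] <= 1e-5) || any(par[4:6] <= 1e-3)) return(1e9)
      ## the three center distances must form a (possibly degenerate)
      ## triangle, or no 2D zone layout exists
      if (2 * max(par[4:6]) - sum(par[4:6]) > 0) return(1e9)
      .pairBinnedNll(cn$rg, ed$rg, par[4], par[1], par[2]) +
        .pairBinnedNll(cn$rb, ed$rb, par[5], par[1], par[3]) +
        .pairBinnedNll(cn$gb, ed$gb, par[6], par[2], par[3])
    }
    p0 <- c(pmax(attr(rad0, "unclamped"), 0.02 * max(cd0)) * 1.15, cd0)
    ## optimize on the log scale (parameters are positive and span scales)
    lnll <- function(lpar) nll(exp(lpar))
    best <- NULL
    for (init in list(p0,
                      p0 * c(1.2, 1.4, 1.1, 1, 1, 1),
                      p0 * c(0.9, 0.8, 0.95, 1, 1, 1))) {
      fit <- stats::optim(log(init), lnll, method = "Nelder-Mead",
                          control = list(maxit = 2500, reltol = 1e-10))
      fit <- stats::optim(fit$par, lnll, method = "Nelder-Mead",
                          control = list(maxit = 2500, reltol = 1e-10))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    best$par <- exp(best$par)
    raw <- stats::setNames(best$par[1:3], LOCI)
    radii <- pmax(raw, 0)
    cd0 <- stats::setNames(best$par[4:6], PAIRS)
  }

  centers <- szCenters(cd0)
  new("SurvivalZoneModel",
      radii = radii,
      radiiUnclamped = stats::setNames(as.numeric(raw), LOCI),
      clamped = stats::setNames(as.numeric(raw) < 0, LOCI),
      centers = centers,
      centerDistances = cd0,
      extremes = ext,
      method = method,
      n = nrow(triples))
}

#' Reconstruct per-cell 2D locus positions inside the survival zones
#'
#' Each distance triple defines a triangle (up to rigid motion and
#' reflection).  The triangle is embedded in 2D and rigidly aligned -
#' rotation, translation and, if it lowers the residual, reflection - to
#' minimize the summed squared deviations of its vertices from the fitted
#' zone centers (an orthogonal-Procrustes alignment).  Cells violating the
#' triangle inequality beyond \code{tol} are skipped.
#'
#' @param triples matrix of distance triples (columns \code{rg}, \code{rb},
#'   \code{gb}).
#' @param model a fitted \linkS4class{SurvivalZoneModel}.
#' @param tol relative triangle-inequality tolerance.
#' @return data.frame with one row per reconstructed locus position:
#'   \code{cell}, \code{locus}, \code{x}, \code{y}, \code{residual} (per
#'   cell, repeated), and \code{outside} (TRUE when the point falls outside
#'   its zone circle); skipped cells are listed in attribute
#'   \code{"skipped"}.
#' @export
reconstructPositions <- function(triples, model, tol = 1e-6) {
  triples <- as.matrix(triples)
  centers <- model@centers
  out <- vector("list", nrow(triples))
  skipped <- integer(0)
  ctr_mean <- colMeans(centers)
  C0 <- sweep(centers, 2, ctr_mean)
  for (i in seq_len(nrow(triples))) {
    dd <- triples[i, PAIRS]
    s <- max(dd)
    if (s > 0 && (2 * s - sum(dd)) > tol * s) {
      skipped <- c(skipped, i)
      next
    }
    V <- tryCatch(szCenters(dd), error = function(e) NULL)
    if (is.null(V)) { skipped <- c(skipped, i); next }
    V0 <- sweep(V, 2, colMeans(V))
    ## Kabsch with optional reflection
    best <- NULL
    H <- t(V0) %*% C0
    sv <- svd(H)
    for (refl in c(1, -1)) {
      D <- diag(c(1, refl))
      Rm <- sv$v %*% D %*% t(sv$u)
      Vr <- V0 %*% t(Rm)
      resid <- sum((Vr - C0)^2)
      if (is.null(best) || resid < best$resid)
        best <- list(V = sweep(Vr, 2, ctr_mean, "+"), resid = resid)
    }
    rr <- sqrt(rowSums((best$V - centers)^2))
    out[[i]] <- data.frame(
      cell = i, locus = LOCI, x = best$V[, 1], y = best$V[, 2],
      residual = best$resid,
      outside = rr > model@radii[LOCI],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame()
  attr(res, "skipped") <- skipped
  res
}

#' 2D kernel density of reconstructed locus positions
#'
#' Gaussian-kernel density per locus on a common grid, renormalized so each
#' locus integrates to 1 over the grid.
#'
#' @param points data.frame with columns \code{locus}, \code{x}, \code{y}
#'   (e.g. from [reconstructPositions()]).
#' @param bandwidth kernel bandwidth (one value, used for both axes); by
#'   default a normal-reference bandwidth per locus.
#' @param gridsize number of grid points per axis.
#' @param expand fractional margin added around the data range.
#' @return list per locus of lists with \code{x}, \code{y}, \code{z}
#'   (density matrix) plus the common \code{xlim}/\code{ylim}.
#' @export
positionDensity <- function(points, bandwidth = NULL, gridsize = 101L,
                            expand = 0.25) {
  counts <- table(points$locus)
  if (any(counts < 5))
    stop("need at least 5 points per locus for density estimation")
  rng_x <- range(points$x); rng_y <- range(points$y)
  mx <- diff(rng_x) * expand + 1e-6
  my <- diff(rng_y) * expand + 1e-6
  lims <- c(rng_x[1] - mx, rng_x[2] + mx, rng_y[1] - my, rng_y[2] + my)
  out <- list()
  for (l in unique(points$locus)) {
    px <- points$x[points$locus == l]
    py <- points$y[points$locus == l]
    h <- if (is.null(bandwidth)) {
      hh <- c(tryCatch(MASS::bandwidth.nrd(px), error = function(e) 0),
              tryCatch(MASS::bandwidth.nrd(py), error = function(e) 0))
      hh[hh <= 0] <- diff(range(lims)) / 50
      hh
    } else rep(bandwidth, 2)
    kd <- MASS::kde2d(px, py, h = h, n = gridsize, lims = lims)
    cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    kd$z <- kd$z / (sum(kd$z) * cell)
    out[[l]] <- kd
  }
  attr(out, "xlim") <- lims[1:2]
  attr(out, "ylim") <- lims[3:4]
  out
}
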