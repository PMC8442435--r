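#' Empirical cumulative distribution on a grid
#'
#' Right-continuous step CDF of a sample, evaluated at \code{grid}.
#'
#' @param values non-empty numeric sample.
#' @param grid evaluation points (default: sorted unique values).
#' @return data.frame with columns \code{x} and \code{cdf}.
#' @export
empiricalCdf <- function(values, grid = NULL) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty sample")
  if (is.null(grid)) grid <- sort(unique(values))
  F <- stats::ecdf(values)
  data.frame(x = grid, cdf = F(grid))
}

#' Analytic radial null for uniform points in a sphere
#'
#' For points uniformly distributed in a sphere, the normalized radial
#' position d has cumulative distribution P(X < d) = d^3 on [0, 1].
#'
#' @param d normalized radial positions in [0, 1].
#' @return probabilities d^3.
#' @examples
#' randomRadialCdf(0.5)  # 0.125
#' @export
randomRadialCdf <- function(d) {
  if (any(d < 0 | d > 1)) stop("d must be in [0, 1]")
  d^3
}

#' Two-sample comparison of distance or radial-position samples
#'
#' Two-sided two-sample test on the raw measurement values.  The default is
#' the pooled-variance Student t-test; Welch and Kolmogorov-Smirnov
#' variants are available.
#'
#' @param x,y numeric samples.
#' @param method \code{"student"} (pooled variance), \code{"welch"} or
#'   \code{"ks"}.
#' @return list with \code{statistic}, \code{p.value}, \code{n_x},
#'   \code{n_y}, \code{method} and (for t-tests) \code{mean_x},
#'   \code{mean_y}.
#' @export
compareSamples <- function(x, y, method = c("student", "welch", "ks")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both samples must have at least 2 values")
  if (method == "ks") {
    ht <- suppressWarnings(stats::ks.test(x, y))
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                n_x = length(x), n_y = length(y), method = method))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    ## degenerate constant samples: maximal evidence when the means differ
    eq <- mean(x) == mean(y)
    return(list(statistic = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                p.value = if (eq) 1 else 0,
                n_x = length(x), n_y = length(y), method = method,
                mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = (method == "student"))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n_x = length(x), n_y = length(y), method = method,
       mean_x = mean(x), mean_y = mean(y))
}

#' Radial-position table for a population
#'
#' Normalized radial position of every spot, with nucleus labels, suitable
#' for cumulative-frequency analysis against the d^3 null.
#'
#' @param pop a \linkS4class{FishPopulation}.
#' @return data.frame with one row per spot: \code{nucleus_id},
#'   \code{species}, \code{condition}, \code{channel}, \code{radial}.
#' @export
radialPositions <- function(pop) {
  nuc <- pop@nuclei
  sp <- merge(pop@spots,
              nuc[, c("nucleus_id", "nucleus_cx", "nucleus_cy", "nucleus_cz",
                      "nucleus_radius_um")],
              by = "nucleus_id", sort = FALSE)
  pos <- as.matrix(sp[, c("x_um", "y_um", "z_um")])
  ctr <- as.matrix(sp[, c("nucleus_cx", "nucleus_cy", "nucleus_cz")])
  rad <- sqrt(rowSums((pos - ctr)^2)) / sp$nucleus_radius_um
  rad <- pmin(rad, 1)
  data.frame(nucleus_id = sp$nucleus_id, species = sp$species,
             condition = sp$condition, channel = sp$channel,
             radial = rad, stringsAsFactors = FALSE)
}

#' Holm-adjusted pairwise comparisons of a measure across groups
#'
#' Convenience wrapper running [compareSamples()] for every pair of groups,
#' optionally Holm-correcting the p-values (the default reports raw
#' p-values).
#'
#' @param values numeric measurements.
#' @param groups group labels, same length.
#' @param method test method, see [compareSamples()].
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return data.frame of pairwise results.
#' @export
pairwiseComparisons <- function(values, groups,
                                method = c("student", "welch", "ks"),
                                adjust = c("none", "holm")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  gs <- unique(groups)
  if (length(gs) < 2) stop("need at least two groups")
  cmb <- utils::combn(gs, 2)
  res <- lapply(seq_len(ncol(cmb)), function(k) {
    g1 <- cmb[1, k]; g2 <- cmb[2, k]
    r <- compareSamples(values[groups == g1], values[groups == g2],
                        method = method)
    data.frame(group1 = g1, group2 = g2, statistic = r$statistic,
               p.value = r$p.value, n1 = r$n_x, n2 = r$n_y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "holm") out$p.adjusted <- stats::p.adjust(out$p.value, "holm")
  out
}
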