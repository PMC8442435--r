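#' Cumulative-frequency plot with the uniform-sphere null
#'
#' Empirical cumulative frequency curves of a dimensionless measure (radial
#' position or normalized distance) per group, with the analytic random
#' radial null \eqn{P(X < d) = d^3} overlaid when requested.
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @param showNull overlay the d^3 curve (appropriate for radial positions).
#' @param xlab x-axis label.
#' @return a ggplot object.
#' @export
plotCumulativeFrequency <- function(values, groups,
                                    showNull = TRUE,
                                    xlab = "normalized measure") {
  df <- data.frame(value = values, group = as.character(groups))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                        colour = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = xlab, y = "cumulative frequency", colour = NULL) +
    ggplot2::theme_classic()
  if (showNull) {
    grid <- seq(0, 1, length.out = 200)
    nulldf <- data.frame(value = grid, cdf = randomRadialCdf(grid))
    p <- p + ggplot2::geom_line(
      data = nulldf,
      ggplot2::aes(x = .data$value, y = .data$cdf),
      inherit.aes = FALSE, colour = "black", linetype = 2)
  }
  p
}

#' Bar chart of nucleus pattern fractions
#'
#' @param ... named \linkS4class{PatternCounts} objects (names become panel
#'   labels, e.g. \code{resting = pcR, activated = pcA}).
#' @return a ggplot object.
#' @export
plotPatternBars <- function(...) {
  pcs <- list(...)
  if (is.null(names(pcs)) || any(names(pcs) == ""))
    names(pcs) <- paste0("group", seq_along(pcs))
  rows <- lapply(names(pcs), function(nm) {
    v <- as.vector(pcs[[nm]])
    if (sum(v) == 0) return(NULL)  # nothing informative to draw
    data.frame(group = nm, pattern = c("C-C", "C-D", "D-D"),
               fraction = v / sum(v), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no informative pattern counts to plot")
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$fraction,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "nuclei", fill = NULL) +
    ggplot2::theme_classic()
}

#' Survival-zone plot: circles, reconstructed points, density contours
#'
#' @param model a fitted \linkS4class{SurvivalZoneModel}.
#' @param points optional reconstruction from [reconstructPositions()].
#' @param contours overlay kernel-density contours of the points.
#' @return a ggplot object.
#' @export
plotSurvivalZones <- function(model, points = NULL, contours = TRUE) {
  cen <- model@centers
  theta <- seq(0, 2 * pi, length.out = 181)
  circ <- do.call(rbind, lapply(LOCI, function(l) {
    data.frame(locus = l,
               x = cen[l, 1] + model@radii[l] * cos(theta),
               y = cen[l, 2] + model@radii[l] * sin(theta))
  }))
  cols <- c(r = "red3", g = "green4", b = "blue3")
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$locus),
                       linetype = 3, linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (normalized)", y = "y (normalized)",
                  colour = "locus") +
    ggplot2::theme_classic()
  if (!is.null(points) && nrow(points)) {
    p <- p + ggplot2::geom_point(
      data = points, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$locus),
      size = 0.5, alpha = 0.35)
    if (contours)
      p <- p + ggplot2::geom_density_2d(
        data = points, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$locus),
        linewidth = 0.3, bins = 6)
  }
  p
}
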