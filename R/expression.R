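#' qPCR amplification efficiency from a dilution series
#'
#' Least-squares slope of Ct against log10(dilution); the efficiency is
#' \eqn{E = 10^{-1/slope}}.  A perfect doubling assay has slope -3.3219 and
#' E = 2.  A warning is issued when E falls outside [1.8, 2.2]; a
#' non-negative slope (Ct not decreasing with template amount) is an error.
#'
#' @param dilution strictly positive dilution factors (relative template
#'   amounts), at least 3 points.
#' @param ct threshold-cycle values.
#' @return efficiency E, with attributes \code{"slope"} and
#'   \code{"r.squared"}.
#' @examples
#' d <- c(1, 1/5, 1/10, 1/20, 1/40, 1/80)
#' efficiencyFromDilutions(d, 20 - log2(d))  # E = 2
#' @export
efficiencyFromDilutions <- function(dilution, ct) {
  if (length(dilution) != length(ct)) stop("dilution and ct lengths differ")
  if (length(dilution) < 3) stop("need at least 3 dilution points")
  if (any(dilution <= 0)) stop("dilutions must be strictly positive")
  fit <- stats::lm(ct ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("Ct does not decrease with template amount (slope >= 0)")
  E <- 10^(-1 / slope)
  if (E <= 1 || E > 2.5)
    stop(sprintf("implausible efficiency E = %.3f (slope %.3f)", E, slope))
  if (E < 1.8 || E > 2.2)
    warning(sprintf("efficiency E = %.3f outside the usual [1.8, 2.2] range", E))
  attr(E, "slope") <- slope
  attr(E, "r.squared") <- suppressWarnings(summary(fit)$r.squared)
  E
}

#' Pfaffl relative expression ratio
#'
#' Efficiency-corrected relative expression of a target gene against a
#' reference gene:
#' \deqn{ratio = E_{target}^{\Delta Ct_{target}} / E_{ref}^{\Delta Ct_{ref}}}
#' where \eqn{\Delta Ct = Ct(calibrator) - Ct(sample)} for each gene.
#'
#' @param eTarget,eRef amplification efficiencies (> 1).
#' @param dCtTarget,dCtRef \eqn{\Delta Ct} values (calibrator minus sample).
#' @return the relative expression ratio.
#' @examples
#' pfafflRatio(2, 3, 2, 0)  # 8
#' @export
pfafflRatio <- function(eTarget, dCtTarget, eRef, dCtRef) {
  if (any(c(eTarget, eRef) <= 1))
    stop("efficiencies must be > 1")
  eTarget^dCtTarget / eRef^dCtRef
}
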