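#' Pair the six spots of a nucleus into two alleles
#'
#' With two spots per channel there are four distinct ways to split the six
#' spots into two one-per-channel triplets.  The partition minimizing the
#' total within-triplet pairwise distance is chosen; the nucleus is rejected
#' when the best and second-best partitions are not clearly differentiated
#' (relative score gap below \code{separabilityMargin}), or when any channel
#' does not have exactly two spots.
#'
#' @param spots data.frame of the spots of one nucleus (columns
#'   \code{channel}, \code{x_um}, \code{y_um}, \code{z_um},
#'   \code{spot_radius_um}).
#' @param separabilityMargin minimum relative gap between the best and
#'   second-best partition scores.
#' @return a list with \code{ok} (logical), \code{reason} (when rejected),
#'   and when paired: \code{alleles}, a list of two alleles, each holding
#'   \code{positions} (3x3 matrix, rows \code{classI}, \code{classII},
#'   \code{classIII}), \code{radii}, \code{distances} (named \code{d_I_II},
#'   \code{d_I_III}, \code{d_II_III}, \eqn{\mu m}) and \code{rows} (row
#'   indices into \code{spots}); plus the partition \code{scores}.
#' @export
pairSpots <- function(spots, separabilityMargin = 0.2) {
  byc <- split(seq_len(nrow(spots)), spots$channel)
  if (!identical(sort(names(byc)), sort(CHANNELS)) ||
      !all(lengths(byc[CHANNELS]) == 2L)) {
    return(list(ok = FALSE, reason = "need exactly 2 spots per channel"))
  }
  pos <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  tripletScore <- function(rows) {
    p <- pos[rows, , drop = FALSE]
    sum(stats::dist(p))
  }
  ## enumerate: fix classI spot 1 in allele 1, choose classII and classIII mates
  combos <- expand.grid(ii = 1:2, iii = 1:2)
  scores <- numeric(4)
  parts <- vector("list", 4)
  for (k in seq_len(4)) {
    a1 <- c(byc$classI[1], byc$classII[combos$ii[k]], byc$classIII[combos$iii[k]])
    a2 <- c(byc$classI[2], byc$classII[3 - combos$ii[k]], byc$classIII[3 - combos$iii[k]])
    scores[k] <- tripletScore(a1) + tripletScore(a2)
    parts[[k]] <- list(a1, a2)
  }
  ord <- order(scores)
  best <- scores[ord[1]]
  second <- scores[ord[2]]
  gap <- (second - best) / max(best, .Machine$double.eps)
  if (gap < separabilityMargin)
    return(list(ok = FALSE, scores = scores,
                reason = sprintf(
                  "alleles not clearly differentiated (relative score gap %.3f < %.3f)",
                  gap, separabilityMargin)))
  mkAllele <- function(rows) {
    ord2 <- rows[match(CHANNELS, spots$channel[rows])]
    p <- pos[ord2, , drop = FALSE]
    rownames(p) <- CHANNELS
    r <- spots$spot_radius_um[ord2]
    names(r) <- CHANNELS
    d <- c(
      d_I_II = sqrt(sum((p["classI", ] - p["classII", ])^2)),
      d_I_III = sqrt(sum((p["classI", ] - p["classIII", ])^2)),
      d_II_III = sqrt(sum((p["classII", ] - p["classIII", ])^2))
    )
    list(positions = p, radii = r, distances = d, rows = ord2)
  }
  list(ok = TRUE,
       alleles = lapply(parts[[ord[1]]], mkAllele),
       scores = scores)
}

#' Classify an allele as compacted or decompacted
#'
#' Each of the three locus pairs has threshold \eqn{r_i + r_j}, the sum of
#' the two spot radii (equal to \eqn{2r} when a single radius is used).
#' The allele is decompacted (\code{"D"}) when every pairwise distance is at
#' least its threshold, compacted (\code{"C"}) when every pairwise distance
#' is below its threshold, and \code{"ambiguous"} otherwise (mixed pairs;
#' excluded from pattern counts by default).  Distances and radii are
#' physical (\eqn{\mu m}).
#'
#' @param allele an allele as returned by [pairSpots()], or a list with
#'   \code{distances} (named \code{d_I_II}, \code{d_I_III}, \code{d_II_III})
#'   and \code{radii} (named by channel).
#' @param rule \code{"pairwise"} (per-pair \eqn{r_i + r_j} thresholds) or
#'   \code{"majority"} (state of the majority of pairs; no ambiguity except
#'   exact balance, which cannot occur with three pairs).
#' @return \code{"C"}, \code{"D"} or \code{"ambiguous"}.
#' @export
classifyAllele <- function(allele, rule = c("pairwise", "majority")) {
  rule <- match.arg(rule)
  r <- allele$radii
  if (is.null(r) || any(is.na(r)))
    stop("spot radii are required to classify an allele")
  d <- allele$distances
  thr <- c(
    d_I_II = unname(r["classI"] + r["classII"]),
    d_I_III = unname(r["classI"] + r["classIII"]),
    d_II_III = unname(r["classII"] + r["classIII"])
  )
  sep <- d[names(thr)] >= thr
  if (rule == "majority")
    return(if (sum(sep) >= 2) "D" else "C")
  if (all(sep)) "D" else if (!any(sep)) "C" else "ambiguous"
}

#' Nucleus pattern from two allele states
#'
#' @param s1,s2 allele states (\code{"C"}, \code{"D"} or
#'   \code{"ambiguous"}).
#' @return \code{"C-C"}, \code{"C-D"}, \code{"D-D"} or \code{"excluded"}
#'   (any ambiguous allele excludes the nucleus).  The pattern is an
#'   unordered pair: \code{(D, C)} and \code{(C, D)} both give
#'   \code{"C-D"}.
#' @export
nucleusPattern <- function(s1, s2) {
  if (s1 == "ambiguous" || s2 == "ambiguous") return("excluded")
  paste(sort(c(s1, s2)), collapse = "-")
}

#' Theoretical nucleus-pattern probabilities
#'
#' Enumerates the states of two independent alleles, each equally likely to
#' be compacted or decompacted, and collapses ordered pairs to unordered
#' patterns: P(C-C) = P(D-D) = 1/4 and P(C-D) = 1/2.
#'
#' @return named probabilities \code{CC}, \code{CD}, \code{DD}.
#' @export
theoreticalPatternProbs <- function() {
  states <- expand.grid(a1 = c("C", "D"), a2 = c("C", "D"),
                        stringsAsFactors = FALSE)
  pat <- apply(states, 1, function(s) paste(sort(s), collapse = "-"))
  tab <- table(factor(pat, levels = c("C-C", "C-D", "D-D"))) / nrow(states)
  stats::setNames(as.numeric(tab), c("CC", "CD", "DD"))
}

#' Count nucleus compaction patterns in a population
#'
#' Pairs the spots of every nucleus, classifies both alleles and tallies the
#' C-C / C-D / D-D patterns.  Nuclei that fail pairing or contain an
#' ambiguous allele are counted as excluded.
#'
#' @param pop a \linkS4class{FishPopulation}.
#' @param separabilityMargin relative margin for [pairSpots()].
#' @param rule classification rule, see [classifyAllele()].
#' @return a \linkS4class{PatternCounts}; the per-nucleus patterns are in
#'   attribute \code{"patterns"} and exclusion reasons in attribute
#'   \code{"exclusions"}.
#' @export
patternCounts <- function(pop, separabilityMargin = 0.2,
                          rule = c("pairwise", "majority")) {
  rule <- match.arg(rule)
  nuc <- pop@nuclei
  patterns <- character(nrow(nuc))
  reasons <- character(nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    sp <- pop@spots[pop@spots$nucleus_id == nuc$nucleus_id[i], ]
    pr <- pairSpots(sp, separabilityMargin = separabilityMargin)
    if (!pr$ok) {
      patterns[i] <- "excluded"
      reasons[i] <- pr$reason
      next
    }
    st <- vapply(pr$alleles, classifyAllele, character(1), rule = rule)
    patterns[i] <- nucleusPattern(st[1], st[2])
    if (patterns[i] == "excluded") reasons[i] <- "ambiguous allele state"
  }
  tab <- table(factor(patterns, levels = c("C-C", "C-D", "D-D", "excluded")))
  obj <- new("PatternCounts",
             nCC = as.integer(tab["C-C"]), nCD = as.integer(tab["C-D"]),
             nDD = as.integer(tab["D-D"]), nExcluded = as.integer(tab["excluded"]),
             condition = unique(nuc$condition), species = unique(nuc$species))
  attr(obj, "patterns") <- data.frame(nucleus_id = nuc$nucleus_id,
                                      pattern = patterns,
                                      stringsAsFactors = FALSE)
  attr(obj, "exclusions") <- data.frame(
    nucleus_id = nuc$nucleus_id[patterns == "excluded"],
    reason = reasons[patterns == "excluded"],
    stringsAsFactors = FALSE)
  obj
}

#' Chi-squared goodness-of-fit for given probabilities
#'
#' Pearson goodness-of-fit of observed pattern counts against theoretical
#' probabilities (no continuity correction), as used to test whether the
#' two alleles of a nucleus adopt independent equiprobable states.
#'
#' @param counts non-negative counts.
#' @param probs probabilities summing to 1 (default the theoretical
#'   C-C/C-D/D-D pattern probabilities).
#' @return list with \code{statistic}, \code{df}, \code{p.value} and
#'   \code{expected}.
#' @export
chisqGivenProbs <- function(counts, probs = theoreticalPatternProbs()) {
  counts <- if (is(counts, "PatternCounts")) as.vector(counts) else counts
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive sum")
  if (abs(sum(probs) - 1) > 1e-8) stop("probs must sum to 1")
  if (any(sum(counts) * probs == 0))
    stop("an expected count is zero")
  ht <- stats::chisq.test(x = counts, p = probs)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected)
}

#' Compare pattern distributions between conditions
#'
#' Pearson chi-squared test on the 3 x 2 contingency table of C-C / C-D /
#' D-D counts in two conditions (df = 2, no continuity correction).  A
#' warning is issued when any expected count is below 5.
#'
#' @param resting,activated \linkS4class{PatternCounts} or length-3 count
#'   vectors (CC, CD, DD).
#' @return list with \code{statistic}, \code{df}, \code{p.value} and
#'   \code{expected}.
#' @export
compareConditions <- function(resting, activated) {
  cr <- if (is(resting, "PatternCounts")) as.vector(resting) else resting
  ca <- if (is(activated, "PatternCounts")) as.vector(activated) else activated
  if (sum(cr) == 0 || sum(ca) == 0)
    stop("a condition has zero total count")
  tab <- rbind(resting = cr, activated = ca)
  keep <- colSums(tab) > 0
  if (!all(keep)) {
    if (sum(keep) < 2) stop("degenerate table: fewer than 2 informative patterns")
    tab <- tab[, keep, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5))
    warning("some expected counts are below 5; the chi-squared approximation may be poor")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected)
}
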