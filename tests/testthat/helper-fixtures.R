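# Shared fixtures: all synthetic, built in code.

# A nucleus with two well-separated tight triplets (ground truth: spots
# 1:3 = allele 1, 4:6 = allele 2), jitter in um.
makeTwoTripletNucleus <- function(separation = 5, jitter = 0.15,
                                  spotRadius = 0.25, seed = 1) {
  set.seed(seed)
  base1 <- c(-separation / 2, 0, 0)
  base2 <- c(separation / 2, 0, 0)
  pos <- rbind(
    t(replicate(3, base1 + runif(3, -jitter, jitter))),
    t(replicate(3, base2 + runif(3, -jitter, jitter)))
  )
  data.frame(
    nucleus_id = "nuc1", condition = "resting", species = "pig",
    channel = rep(c("classI", "classII", "classIII"), 2),
    x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
    spot_radius_um = spotRadius,
    stringsAsFactors = FALSE
  )
}

# Independent brute-force spot pairing: enumerate the 4 one-per-channel
# partitions directly and return the best total within-triplet distance
# and the score gap.
bruteForcePairing <- function(spots) {
  byc <- split(seq_len(nrow(spots)), spots$channel)
  pos <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  score3 <- function(rows) sum(dist(pos[rows, ]))
  scores <- c()
  parts <- list()
  for (ii in 1:2) for (iii in 1:2) {
    a1 <- c(byc$classI[1], byc$classII[ii], byc$classIII[iii])
    a2 <- c(byc$classI[2], byc$classII[3 - ii], byc$classIII[3 - iii])
    scores <- c(scores, score3(a1) + score3(a2))
    parts[[length(parts) + 1]] <- list(sort(a1), sort(a2))
  }
  ord <- order(scores)
  list(best = parts[[ord[1]]], scores = scores[ord])
}

# Distance triples sampled from three survival-zone spheres (no nucleus),
# pooled over nAllelesPerCell triples per cell.
sphereModelTriples <- function(nCells, radii, centers,
                               nAllelesPerCell = 2) {
  n <- nCells * nAllelesPerCell
  P <- lapply(c("r", "g", "b"), function(l)
    runifSphere(n, radii[l], centers[[l]]))
  names(P) <- c("r", "g", "b")
  cbind(
    rg = sqrt(rowSums((P$r - P$g)^2)),
    rb = sqrt(rowSums((P$r - P$b)^2)),
    gb = sqrt(rowSums((P$g - P$b)^2))
  )
}

# Well-separated zone-center layout used by recovery checks.
szTestCenters <- list(r = c(0, 0, 0), g = c(2, 0, 0), b = c(1, 1.8, 0))
szTestCenterDistances <- c(rg = 2, rb = sqrt(1 + 1.8^2), gb = sqrt(1 + 1.8^2))

randomExtremes <- function() {
  lo <- runif(3, 0, 2)
  hi <- lo + runif(3, 0, 1.5)
  c(rgmin = lo[1], rgmax = hi[1], rbmin = lo[2], rbmax = hi[2],
    gbmin = lo[3], gbmax = hi[3])
}
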