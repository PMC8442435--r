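test_that("pairwise extremes are per-pair min and max", {
  tr <- rbind(c(rg = 1, rb = 2, gb = 3), c(rg = 2, rb = 1, gb = 4))
  ex <- pairwiseExtremes(tr)
  expect_equal(extremeValues(ex),
               c(rgmin = 1, rgmax = 2, rbmin = 1, rbmax = 2,
                 gbmin = 3, gbmax = 4))
  # identical triples: min = max
  tr2 <- rbind(c(rg = 1, rb = 2, gb = 2.5), c(rg = 1, rb = 2, gb = 2.5))
  e2 <- extremeValues(pairwiseExtremes(tr2))
  expect_equal(e2[c("rgmin", "rbmin", "gbmin")],
               e2[c("rgmax", "rbmax", "gbmax")], ignore_attr = TRUE)
  expect_error(pairwiseExtremes(tr[1, , drop = FALSE]), "at least 2")
  expect_error(pairwiseExtremes(tr, q = 0.6), "q must be")
})

test_that("quantile trimming resists a gross outlier", {
  set.seed(13)
  n <- 500
  clean <- cbind(rg = runif(n, 1, 2), rb = runif(n, 2, 3),
                 gb = runif(n, 1.5, 2.5))
  spoiled <- rbind(clean, c(rg = 50, rb = 50, gb = 50))
  eClean <- extremeValues(pairwiseExtremes(clean, q = 0))
  eTrim <- extremeValues(pairwiseExtremes(spoiled, q = 0.01))
  expect_true(all(abs(eTrim - eClean) / eClean < 0.05))
})

test_that("closed-form radii satisfy the printed formulas", {
  # static loci: every extreme pair collapses, radii vanish
  e0 <- c(rgmin = 1, rgmax = 1, rbmin = 2, rbmax = 2, gbmin = 1.5,
          gbmax = 1.5)
  expect_equal(szRadii(e0), c(r = 0, g = 0, b = 0), ignore_attr = TRUE)
  # direct substitution
  e1 <- c(rgmin = 1, rgmax = 2, rbmin = 2, rbmax = 3, gbmin = 1, gbmax = 2)
  expect_equal(szRadii(e1), c(r = 0.25, g = 0.25, b = 0.25),
               ignore_attr = TRUE)
  # negative values clamp with a warning and keep the raw value
  e2 <- c(rgmin = 1, rgmax = 1.01, rbmin = 1, rbmax = 2.5,
          gbmin = 1, gbmax = 1.01)
  expect_warning(r2 <- szRadii(e2), "clamped")
  expect_true(all(r2 >= 0))
  expect_lt(min(attr(r2, "unclamped")), 0)
})

test_that("radius pair-sums equal half the extreme ranges (algebraic identity)", {
  set.seed(19)
  for (i in 1:200) {
    e <- randomExtremes()
    r <- suppressWarnings(szRadii(e))
    raw <- attr(r, "unclamped")
    expect_equal(raw[["r"]] + raw[["g"]], (e[["rgmax"]] - e[["rgmin"]]) / 2,
                 tolerance = 1e-12)
    expect_equal(raw[["g"]] + raw[["b"]], (e[["gbmax"]] - e[["gbmin"]]) / 2,
                 tolerance = 1e-12)
    expect_equal(raw[["r"]] + raw[["b"]], (e[["rbmax"]] - e[["rbmin"]]) / 2,
                 tolerance = 1e-12)
  }
})

test_that("zone centers are laid out by trilateration in a canonical frame", {
  cen <- szCenters(c(rg = 1, rb = 1, gb = 1))
  expect_equal(cen["r", ], c(x = 0, y = 0))
  expect_equal(cen["g", ], c(x = 1, y = 0))
  expect_equal(cen["b", ], c(x = 0.5, y = sqrt(3) / 2))
  # degenerate collinear layout
  col <- szCenters(c(rg = 1, rb = 3, gb = 2))
  expect_equal(col["b", "y"], 0)
  expect_equal(col["b", "x"], 3)
  expect_error(szCenters(c(rg = 1, rb = 1, gb = 5)), "triangle inequality")
})

test_that("sphere-model simulation recovers center distances and radii", {
  set.seed(1)
  radii <- c(r = 0.10, g = 0.25, b = 0.40)
  tr <- sphereModelTriples(2000, radii, szTestCenters)
  fit <- fitSurvivalZones(tr)
  expect_equal(fit@method, "mle")
  relR <- abs(confinementRadii(fit) - radii) / radii
  expect_lt(max(relR), 0.10)
  relC <- abs(fit@centerDistances - szTestCenterDistances) /
    szTestCenterDistances
  expect_lt(max(relC), 0.05)
  # the observed extremes and the closed form are stored alongside
  expect_s4_class(zoneExtremes(fit), "PairwiseExtremes")
  expect_equal(zoneExtremes(fit)@n, 4000L)
})

test_that("distance triples can be pooled or restricted per allele", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 10, seed = 47))
  both <- alleleDistanceTriples(pop, separabilityMargin = 0)
  one <- alleleDistanceTriples(pop, separabilityMargin = 0, allele = 1)
  expect_equal(nrow(both), 20)
  expect_equal(nrow(one), 10)
  expect_true(all(one %in% both))
  # physical distances are the normalized ones times the diameter
  phys <- alleleDistanceTriples(pop, normalize = FALSE,
                                separabilityMargin = 0)
  R <- nucleusTable(pop)$nucleus_radius_um[1]
  expect_equal(phys[1, ], both[1, ] * 2 * R)
})

test_that("extremes-method radius pair-sums grow monotonically with n", {
  # on nested subsamples the per-pair ranges can only widen, so every
  # radius pair-sum (and the radius total) is non-decreasing; individual
  # radii are differences of ranges and need not be monotone
  set.seed(23)
  tr <- sphereModelTriples(1500, c(r = 0.2, g = 0.2, b = 0.2), szTestCenters)
  sizes <- c(100, 400, 1000, 3000)
  fits <- lapply(sizes, function(k) {
    r <- confinementRadii(fitSurvivalZones(tr[seq_len(k), ],
                                           method = "extremes"))
    c(rg = r[["r"]] + r[["g"]], rb = r[["r"]] + r[["b"]],
      gb = r[["g"]] + r[["b"]], total = sum(r))
  })
  for (i in seq_len(length(sizes) - 1))
    expect_true(all(fits[[i + 1]] >= fits[[i]] - 1e-12))
})

test_that("static input yields the all-zero model", {
  tr <- matrix(rep(c(1, 2, 1.5), each = 3), nrow = 3,
               dimnames = list(NULL, c("rg", "rb", "gb")))
  fit <- fitSurvivalZones(tr, method = "extremes")
  expect_equal(unname(confinementRadii(fit)), c(0, 0, 0))
})

test_that("reconstruction aligns triangles onto the zone centers", {
  cd <- szTestCenterDistances
  model <- fitSurvivalZones(
    rbind(cd + c(0.1, -0.05, 0.02), cd - c(0.1, -0.05, 0.02), cd, cd),
    method = "extremes")
  # a cell whose distances equal the center distances lands on the centers
  rec <- reconstructPositions(rbind(cd), model)
  expect_equal(rec$residual, rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(as.matrix(rec[, c("x", "y")])),
               unname(zoneCenters(model)), tolerance = 1e-6)
})

test_that("mirror-image cells reconstruct with identical residuals", {
  set.seed(3)
  model <- fitSurvivalZones(
    sphereModelTriples(200, c(r = 0.15, g = 0.15, b = 0.15), szTestCenters),
    method = "extremes")
  d <- c(rg = 2.1, rb = 1.9, gb = 2.2)
  rec <- reconstructPositions(rbind(d, d), model)
  expect_equal(rec$residual[1:3], rec$residual[4:6])
  # a triangle-inequality-violating cell is skipped, not an error
  bad <- rbind(d, c(rg = 5, rb = 1, gb = 1))
  rec2 <- reconstructPositions(bad, model)
  expect_equal(attr(rec2, "skipped"), 2L)
})

test_that("reconstructed locus clouds center on their survival zones", {
  set.seed(29)
  radii <- c(r = 0.10, g = 0.25, b = 0.40)
  tr <- sphereModelTriples(2000, radii, szTestCenters)
  model <- fitSurvivalZones(tr)
  rec <- reconstructPositions(tr, model)
  for (l in c("r", "g", "b")) {
    m <- colMeans(rec[rec$locus == l, c("x", "y")])
    expect_lt(sqrt(sum((m - zoneCenters(model)[l, ])^2)), 0.05)
  }
})

test_that("position densities integrate to one and follow the data", {
  set.seed(37)
  pts <- data.frame(
    locus = rep(c("r", "g"), each = 400),
    x = c(rnorm(400, 0, 0.2), runif(400, -1, 1)),
    y = c(rnorm(400, 0, 0.2), runif(400, -1, 1)))
  dens <- positionDensity(pts, gridsize = 81)
  for (l in c("r", "g")) {
    kd <- dens[[l]]
    cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    expect_equal(sum(kd$z) * cell, 1, tolerance = 1e-3)
  }
  # identical points concentrate the mass near that point
  same <- data.frame(locus = "r", x = rep(0.3, 10), y = rep(-0.2, 10))
  d2 <- positionDensity(same, bandwidth = 0.05, gridsize = 81)
  kd <- d2[["r"]]
  peak <- arrayInd(which.max(kd$z), dim(kd$z))
  expect_lt(abs(kd$x[peak[1]] - 0.3), 0.05)
  expect_lt(abs(kd$y[peak[2]] + 0.2), 0.05)
  expect_error(positionDensity(same[1:3, ]), "at least 5")
})
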