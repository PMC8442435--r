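test_that("radial position is the normalized distance to the nucleus center", {
  expect_equal(radialPosition(c(0, 0, 0), c(0, 0, 0), 2), 0)
  expect_equal(radialPosition(c(0, 0, 2), c(0, 0, 0), 2), 1)
  expect_equal(radialPosition(c(0.3, 0.4, 0), c(0, 0, 0), 1), 0.5)
  # off-center nucleus
  expect_equal(radialPosition(c(1.3, 2.4, 5), c(1, 2, 5), 1), 0.5)
  expect_error(radialPosition(c(0, 0, 0), c(0, 0, 0), 0), "radius")
  expect_warning(r <- radialPosition(c(0, 0, 1.02), c(0, 0, 0), 1),
                 "clipped")
  expect_equal(r, 1)
  expect_error(radialPosition(c(0, 0, 2), c(0, 0, 0), 1), "outside")
})

test_that("ellipsoidal envelopes use the local radius along the ray", {
  ax <- c(1, 1, 0.7)
  expect_equal(radialPosition(c(0, 0, 0.35), c(0, 0, 0), 1, semiaxes = ax),
               0.5)
  expect_equal(radialPosition(c(0.5, 0, 0), c(0, 0, 0), 1, semiaxes = ax),
               0.5)
  # unit semiaxes reduce to the spherical case
  p <- c(0.2, -0.3, 0.1)
  expect_equal(radialPosition(p, c(0, 0, 0), 1.5, semiaxes = c(1, 1, 1)),
               radialPosition(p, c(0, 0, 0), 1.5))
  expect_error(radialPosition(p, c(0, 0, 0), 1, semiaxes = c(1, -1, 1)),
               "semiaxes")
})

test_that("normalized pair distance divides by the nucleus diameter", {
  expect_equal(normalizedPairDistance(c(1, 1, 1), c(1, 1, 1), 3), 0)
  expect_equal(normalizedPairDistance(c(0, 0, -2), c(0, 0, 2), 2), 1)
  expect_equal(normalizedPairDistance(c(0, 0, 0), c(1, 0, 0), 2.5), 0.2)
  expect_error(normalizedPairDistance(c(0, 0, 0), c(1, 0, 0), 0), "diameter")
  # symmetry in the spot arguments
  set.seed(7)
  for (i in 1:20) {
    p1 <- rnorm(3); p2 <- rnorm(3); R <- runif(1, 1, 5)
    expect_identical(normalizedPairDistance(p1, p2, R),
                     normalizedPairDistance(p2, p1, R))
  }
})

test_that("internal angles follow the law of cosines with A at class III", {
  expect_equal(internalAngles(1, 1, 1), c(A = 60, B = 60, C = 60))
  expect_equal(internalAngles(2, 1, 1), c(A = 180, B = 0, C = 0))
  # law-of-cosines oracle, recomputed independently
  locOracle <- function(a, b, c) {
    A <- acos((b^2 + c^2 - a^2) / (2 * b * c)) * 180 / pi
    B <- acos((a^2 + c^2 - b^2) / (2 * a * c)) * 180 / pi
    C <- acos((a^2 + b^2 - c^2) / (2 * a * b)) * 180 / pi
    c(A = A, B = B, C = C)
  }
  expect_equal(internalAngles(5, 4, 3)[["A"]], 90, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    s <- sort(runif(3, 0.1, 2))
    if (s[3] >= s[1] + s[2]) next
    got <- internalAngles(s[1], s[2], s[3])
    expect_equal(got, locOracle(s[1], s[2], s[3]), tolerance = 1e-9)
    expect_equal(sum(got), 180, tolerance = 1e-6)
    # invariance to joint rescaling of all sides
    k <- runif(1, 0.1, 10)
    expect_equal(internalAngles(k * s[1], k * s[2], k * s[3]), got,
                 tolerance = 1e-9)
  }
  expect_error(internalAngles(3, 1, 1), "triangle inequality")
})

test_that("degenerate triangles resolve by continuity", {
  # one vanishing side: 0 opposite it, 90 at each endpoint (isoceles limit)
  expect_equal(internalAngles(0, 1, 1), c(A = 0, B = 90, C = 90))
  expect_equal(internalAngles(1, 0, 1), c(A = 90, B = 0, C = 90))
  # continuity: a tiny side approaches that limit
  near <- internalAngles(1e-9, 1, 1)
  expect_lt(abs(near[["A"]] - 0), 1e-3)
  # all-zero triangle: equilateral by scale invariance
  expect_equal(internalAngles(0, 0, 0), c(A = 60, B = 60, C = 60))
})

test_that("radial positions of uniform sphere points follow the cubic null", {
  set.seed(5000)
  p <- runifSphere(5000, 1)
  r <- radialPosition(p, c(0, 0, 0), 1)
  grid <- seq(0, 1, length.out = 512)
  ks <- max(abs(empiricalCdf(r, grid)$cdf - randomRadialCdf(grid)))
  expect_lt(ks, 0.05)
})

test_that("triangleMetrics produces one consistent row per allele", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 12, seed = 3))
  tm <- triangleMetrics(pop)
  expect_true(nrow(tm) + 2 * length(attr(tm, "excluded")) == 24)
  expect_true(all(abs(tm$A + tm$B + tm$C - 180) < 1e-6))
  expect_true(all(tm[c("a", "b", "c")] >= 0))
  expect_true(all(tm[c("radial_classI", "radial_classII",
                       "radial_classIII")] <= 1))
  # pooled option returns per-nucleus means
  tmp <- triangleMetrics(pop, pooled = TRUE)
  pooled <- attr(tmp, "pooled")
  one <- tmp[tmp$nucleus_id == pooled$nucleus_id[1], ]
  expect_equal(pooled$a[1], mean(one$a))
})
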