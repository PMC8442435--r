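test_that("a fully compacted, noise-free population classifies all-C", {
  cfg <- simulationConfig(nNuclei = 20, seed = 2, fracDecompacted = 0,
                          measurementNoiseSd = 0)
  pop <- simulatePopulation(cfg, "resting")
  for (id in nucleusTable(pop)$nucleus_id) {
    sp <- spotTable(pop)[spotTable(pop)$nucleus_id == id, ]
    pr <- pairSpots(sp)
    expect_true(pr$ok)
    expect_equal(vapply(pr$alleles, classifyAllele, character(1)),
                 c("C", "C"))
  }
})

test_that("simulation is deterministic and extensible under a fixed seed", {
  cfg <- simulationConfig(nNuclei = 75, seed = 123)
  p1 <- simulatePopulation(cfg, "resting")
  expect_equal(nNuclei(p1), 75)
  expect_equal(nrow(spotTable(p1)), 450)
  p2 <- simulatePopulation(cfg, "resting")
  expect_identical(spotTable(p1), spotTable(p2))
  expect_identical(nucleusTable(p1), nucleusTable(p2))
  # one sub-stream per nucleus: extending the population leaves the
  # earlier nuclei untouched
  p3 <- simulatePopulation(simulationConfig(nNuclei = 80, seed = 123),
                           "resting")
  expect_equal(spotTable(p3)[seq_len(450), ], spotTable(p1),
               ignore_attr = TRUE)
})

test_that("all simulated spots lie inside their nucleus", {
  cfg <- simulationConfig(nNuclei = 40, seed = 8, measurementNoiseSd = 0.15)
  for (cond in c("resting", "activated")) {
    pop <- simulatePopulation(cfg, cond)
    sp <- merge(spotTable(pop), nucleusTable(pop), by = "nucleus_id")
    d <- sqrt((sp$x_um - sp$nucleus_cx)^2 + (sp$y_um - sp$nucleus_cy)^2 +
              (sp$z_um - sp$nucleus_cz)^2)
    expect_true(all(d <= sp$nucleus_radius_um + 1e-9))
  }
})

test_that("the decompacted fraction converges to its parameter", {
  cfg <- simulationConfig(nNuclei = 2000, seed = 77, fracDecompacted = 0.35)
  pop <- simulatePopulation(cfg, "resting")
  st <- groundTruth(pop)$alleleStates$state
  phat <- mean(st == "D")
  # binomial 99% CI around the true parameter at n = 4000 alleles
  ci <- 0.35 + c(-1, 1) * qnorm(0.995) * sqrt(0.35 * 0.65 / length(st))
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("a config whose survival zones cannot fit is rejected by name", {
  expect_error(
    simulationConfig(seed = 1, szRadii = c(r = 0.8, g = 0.6, b = 4.5)),
    "survival zone 'b'")
})

test_that("the generator's survival-zone radii are recovered by the fit", {
  # static-geometry population: equal 0.3 um zones, no noise, fixed nucleus
  cfg <- simulationConfig(
    nNuclei = 2000, seed = 1, fracDecompacted = 1,
    measurementNoiseSd = 0, nucleusRadiusSd = 0,
    szRadii = c(r = 0.3, g = 0.3, b = 0.3))
  pop <- simulatePopulation(cfg, "resting")
  triples <- alleleDistanceTriples(pop, normalize = FALSE)
  fit <- fitSurvivalZones(triples)
  rel <- abs(confinementRadii(fit) - 0.3) / 0.3
  expect_lt(max(rel), 0.10)
})
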