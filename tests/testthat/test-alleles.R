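test_that("spot pairing picks the tight-triplet partition", {
  sp <- makeTwoTripletNucleus()
  pr <- pairSpots(sp)
  expect_true(pr$ok)
  got <- lapply(pr$alleles, function(a) sort(a$rows))
  oracle <- bruteForcePairing(sp)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(oracle$best, paste, collapse = ","))
})

test_that("spot pairing agrees with brute-force enumeration on simulated nuclei", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 30, seed = 17))
  for (id in nucleusTable(pop)$nucleus_id) {
    sp <- spotTable(pop)[spotTable(pop)$nucleus_id == id, ]
    pr <- pairSpots(sp, separabilityMargin = 0)
    oracle <- bruteForcePairing(sp)
    expect_true(pr$ok)
    got <- lapply(pr$alleles, function(a) sort(a$rows))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle$best, paste, collapse = ","))
  }
})

test_that("ties and missing spots are rejected", {
  # octahedral configuration: every one-per-channel partition has the same
  # total within-triplet distance, so no pairing is clearly differentiated
  sp <- makeTwoTripletNucleus()
  sp$x_um <- c(1, -1, 0, 0, 0, 0)
  sp$y_um <- c(0, 0, 1, -1, 0, 0)
  sp$z_um <- c(0, 0, 0, 0, 1, -1)
  sp$channel <- rep(c("classI", "classII", "classIII"), each = 2)
  expect_false(pairSpots(sp)$ok)
  # a channel with a single spot
  sp2 <- makeTwoTripletNucleus()[-1, ]
  r <- pairSpots(sp2)
  expect_false(r$ok)
  expect_match(r$reason, "2 spots per channel")
})

test_that("allele classification uses per-pair radius-sum thresholds", {
  mk <- function(d, r = 0.1) list(
    distances = c(d_I_II = d[1], d_I_III = d[2], d_II_III = d[3]),
    radii = c(classI = r, classII = r, classIII = r))
  expect_equal(classifyAllele(mk(c(0.5, 0.6, 0.7))), "D")
  expect_equal(classifyAllele(mk(c(0.05, 0.1, 0.15))), "C")
  expect_equal(classifyAllele(mk(c(0.05, 0.5, 0.5))), "ambiguous")
  # majority rule resolves mixed states
  expect_equal(classifyAllele(mk(c(0.05, 0.5, 0.5)), rule = "majority"), "D")
  expect_equal(classifyAllele(mk(c(0.05, 0.1, 0.5)), rule = "majority"), "C")
  # boundary: distance exactly at threshold counts as separated
  expect_equal(classifyAllele(mk(c(0.2, 0.2, 0.2))), "D")
  # unequal radii: thresholds are r_i + r_j per pair
  al <- list(distances = c(d_I_II = 0.35, d_I_III = 0.45, d_II_III = 0.55),
             radii = c(classI = 0.1, classII = 0.2, classIII = 0.3))
  expect_equal(classifyAllele(al), "D")  # thresholds 0.3, 0.4, 0.5
  expect_error(classifyAllele(list(distances = c(d_I_II = 1, d_I_III = 1,
                                                 d_II_III = 1))),
               "radii")
})

test_that("classification is invariant to channel relabeling with equal radii", {
  set.seed(31)
  for (i in 1:25) {
    d <- runif(3, 0, 0.6)
    r <- 0.12
    states <- sapply(list(d, d[c(2, 3, 1)], d[c(3, 1, 2)]), function(dd)
      classifyAllele(list(
        distances = c(d_I_II = dd[1], d_I_III = dd[2], d_II_III = dd[3]),
        radii = c(classI = r, classII = r, classIII = r))))
    expect_equal(length(unique(states)), 1)
  }
})

test_that("nucleus patterns are unordered and exclude ambiguity", {
  expect_equal(nucleusPattern("C", "D"), "C-D")
  expect_equal(nucleusPattern("D", "C"), "C-D")
  expect_equal(nucleusPattern("C", "C"), "C-C")
  expect_equal(nucleusPattern("D", "D"), "D-D")
  expect_equal(nucleusPattern("C", "ambiguous"), "excluded")
})

test_that("theoretical pattern probabilities come from state enumeration", {
  p <- theoreticalPatternProbs()
  expect_equal(p[["CD"]], 0.50)
  expect_equal(p[["CC"]], 0.25)
  expect_equal(p[["DD"]], 0.25)
  expect_equal(sum(p), 1)
})

test_that("goodness-of-fit chi-squared matches hand computation", {
  r <- chisqGivenProbs(c(25, 50, 25), c(0.25, 0.5, 0.25))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  r2 <- chisqGivenProbs(c(53, 47), c(0.5, 0.5))
  expect_equal(r2$statistic, (3^2 + 3^2) / 50)  # = 0.36
  r3 <- chisqGivenProbs(c(60, 40), c(0.5, 0.5))
  expect_equal(r3$statistic, 4)
  expect_equal(r3$p.value, pchisq(4, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(r3$p.value - 0.0455), 5e-4)
  expect_error(chisqGivenProbs(c(10, 10), c(1, 0)), "zero")
  expect_error(chisqGivenProbs(c(0, 0), c(0.5, 0.5)), "positive sum")
})

test_that("condition comparison is a 3x2 Pearson contingency test", {
  same <- compareConditions(c(30, 40, 30), c(30, 40, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  diff <- compareConditions(c(30, 40, 30), c(10, 30, 60))
  expect_equal(diff$df, 2)
  expect_lt(diff$p.value, 0.01)
  # independent recomputation of the Pearson statistic
  tab <- rbind(c(30, 40, 30), c(10, 30, 60))
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(diff$statistic, sum((tab - exp_)^2 / exp_), tolerance = 1e-12)
  expect_error(compareConditions(c(0, 0, 0), c(1, 2, 3)), "zero total")
})

test_that("pattern counts conserve the number of nuclei", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 50, seed = 41))
  pc <- patternCounts(pop)
  expect_equal(pc@nCC + pc@nCD + pc@nDD + pc@nExcluded, 50L)
  pats <- attr(pc, "patterns")
  expect_equal(nrow(pats), 50)
  expect_equal(sum(pats$pattern == "excluded"), pc@nExcluded)
})
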