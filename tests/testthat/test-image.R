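test_that("rendered blobs peak at the spot position", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 1, seed = 6,
                                             measurementNoiseSd = 0))
  st <- renderImage(pop)
  sp <- spotTable(pop)
  vx <- attr(st, "voxelSize")
  org <- attr(st, "origin")
  for (ch in 1:3) {
    chan <- c("classI", "classII", "classIII")[ch]
    vol <- st[, , , ch]
    am <- arrayInd(which.max(vol), dim(vol))
    peak_um <- voxelToPhysical(am - 1, vx) + org
    true <- sp[sp$channel == chan, c("x_um", "y_um", "z_um")]
    best <- min(sqrt(colSums((t(as.matrix(true)) - as.numeric(peak_um))^2)))
    expect_lt(best, max(vx))  # within one voxel pitch of a true spot
  }
})

test_that("an empty record renders an all-zero stack", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 1, seed = 6))
  pop@spots <- pop@spots[0, ]
  st <- renderImage(pop)
  expect_true(all(st == 0))
  det <- suppressWarnings(detectSpots(st, threshold = 0.1))
  expect_equal(nrow(det), 0)
  expect_warning(
    detectSpots(st[, , , 1], voxelSize = attr(st, "voxelSize"),
                threshold = 0.1),
    "no component above threshold")
})

test_that("spot detection counts well-separated components", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 1, seed = 6,
                                             measurementNoiseSd = 0))
  st <- renderImage(pop)
  det <- suppressWarnings(detectSpots(st))
  expect_equal(unname(table(det$channel)[c("classI", "classII", "classIII")]),
               rep(2L, 3), ignore_attr = TRUE)
})

test_that("render then detect recovers centroids within one voxel per axis", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 3, seed = 10,
                                             measurementNoiseSd = 0))
  for (id in nucleusTable(pop)$nucleus_id) {
    st <- renderImage(pop, id)
    vx <- attr(st, "voxelSize")
    det <- detectSpots(st)
    sp <- spotTable(pop)[spotTable(pop)$nucleus_id == id, ]
    expect_equal(nrow(det), 6)
    for (k in seq_len(nrow(sp))) {
      cand <- det[det$channel == sp$channel[k], ]
      err <- abs(cbind(cand$x_um - sp$x_um[k], cand$y_um - sp$y_um[k],
                       cand$z_um - sp$z_um[k]))
      best <- which.min(rowSums(err^2))
      expect_true(all(err[best, ] <= vx))
    }
  }
})

test_that("estimated spot radius tracks the rendered blob half-width", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 1, seed = 12,
                                             measurementNoiseSd = 0))
  st <- renderImage(pop)
  det <- detectSpots(st)  # default threshold: half maximum
  # the rendered Gaussian has HWHM = spot radius, so the equivalent-sphere
  # radius of the half-maximum region should match the spot radius
  expect_true(all(abs(det$spot_radius_um - 0.25) / 0.25 < 0.25))
})

test_that("stacks round-trip through multi-page TIFF with metadata", {
  pop <- simulatePopulation(simulationConfig(nNuclei = 1, seed = 3))
  st <- renderImage(pop)
  path <- tempfile(fileext = ".tif")
  writeStack(st, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- readStack(path)
  expect_equal(dim(back), dim(st))
  expect_equal(attr(back, "voxelSize"), attr(st, "voxelSize"))
  expect_lt(max(abs(back - st)), max(st) / 2^15)  # 16-bit quantization
})
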