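test_that("infinite SNR gives exactly the projected ground truth", {
  geo <- testGeometry()
  scene <- defaultScene(geo$src, snrDb = Inf, seed = 2L)
  sim <- simulateScene(scene, geo$src, geo$G)
  Y <- matrix(sim$epochs@data[1, , ], nChannels(geo$G))
  expect_identical(Y, gainMatrix(geo$G) %*% sim$Jtrue)
})

test_that("the realised SNR is within half a dB of the request", {
  geo <- testGeometry()
  for (snr in c(0, 10)) {
    scene <- defaultScene(geo$src, snrDb = snr, seed = 4L)
    sim <- simulateScene(scene, geo$src, geo$G)
    Y <- matrix(sim$epochs@data[1, , ], nChannels(geo$G))
    Sg <- gainMatrix(geo$G) %*% sim$Jtrue
    E <- Y - Sg
    tMs <- (seq_len(ncol(Y)) - 1) / scene@sfreq * 1000 +
      scene@epochSpan[1] * 1000
    act <- rep(FALSE, ncol(Y))
    for (p in scene@patches)
      act <- act | (tMs >= p$onsetMs & tMs < p$offsetMs)
    got <- 10 * log10(mean(Sg[, act]^2) / mean(E^2))
    expect_lt(abs(got - snr), 0.5)
  }
})

test_that("simulation is bit-reproducible for a fixed seed", {
  geo <- testGeometry()
  scene <- defaultScene(geo$src, seed = 8L)
  a <- simulateScene(scene, geo$src, geo$G)
  b <- simulateScene(scene, geo$src, geo$G)
  expect_identical(a$epochs@data, b$epochs@data)
  expect_identical(a$Jtrue, b$Jtrue)
  expect_identical(statValues(a$map), statValues(b$map))
})

test_that("the fMRI map is the static union of temporally disjoint patches", {
  geo <- testGeometry()
  pA <- meshPatch(geo$src, 5L, 1L)
  pB <- meshPatch(geo$src, 150L, 1L)
  scene <- simScene(list(
    list(name = "A", vertices = pA, onsetMs = 0, offsetMs = 100,
         waveform = "boxcar"),
    list(name = "B", vertices = pB, onsetMs = 300, offsetMs = 400,
         waveform = "boxcar")),
    epochSpan = c(0, 0.5), sfreq = 500, seed = 1L)
  sim <- simulateScene(scene, geo$src, geo$G)
  expect_true(all(statValues(sim$map)[c(pA, pB)] == 10))
  # static map despite disjoint activity: no sample has both patches on
  onA <- colSums(abs(sim$Jtrue[pA, , drop = FALSE])) > 0
  onB <- colSums(abs(sim$Jtrue[pB, , drop = FALSE])) > 0
  expect_identical(sum(onA & onB), 0L)
  expect_gt(sum(onA), 0L)
  expect_gt(sum(onB), 0L)
})

test_that("patch vertices outside the source space are rejected", {
  geo <- testGeometry()
  scene <- simScene(list(list(vertices = c(1L, 9999L), onsetMs = 0,
                              offsetMs = 100)),
                    epochSpan = c(0, 0.2), seed = 1L)
  expect_error(simulateScene(scene, geo$src, geo$G), "9999")
})

test_that("evaluation metrics are exact on the ground truth itself", {
  geo <- testGeometry()
  scene <- defaultScene(geo$src, seed = 3L)
  sim <- simulateScene(scene, geo$src, geo$G)
  est <- new("SourceEstimate", J = sim$Jtrue,
             sfreq = scene@sfreq, t0 = scene@epochSpan[1],
             windowBoundaries = c(0L, ncol(sim$Jtrue)),
             method = "spatiotemporal")
  rep <- evaluateEstimate(est, sim$Jtrue, scene, geo$src)
  expect_equal(rep@localizationError, rep(0, 3))
  expect_equal(rep@timecourseCorr, rep(1, 3), tolerance = 1e-12)
  expect_identical(rep@energyOutsideTruth, 0)
})

test_that("a known spatial shift is reported as that vertex distance", {
  geo <- testGeometry()
  p <- meshPatch(geo$src, 40L, 0L)          # single-vertex patch
  nb <- adjacency(geo$src)[[40L]][1]        # shift target: a neighbour
  scene <- simScene(list(list(name = "x", vertices = p, onsetMs = 100,
                              offsetMs = 200, waveform = "boxcar")),
                    epochSpan = c(0, 0.3), sfreq = 500, seed = 1L)
  sim <- simulateScene(scene, geo$src, geo$G)
  Jshift <- matrix(0, nrow(sim$Jtrue), ncol(sim$Jtrue))
  Jshift[nb, ] <- sim$Jtrue[40L, ]
  est <- new("SourceEstimate", J = Jshift, sfreq = 500,
             t0 = 0, windowBoundaries = c(0L, ncol(Jshift)),
             method = "spatiotemporal")
  rep <- evaluateEstimate(est, sim$Jtrue, scene, geo$src)
  want <- sqrt(sum((vertices(geo$src)[40L, ] - vertices(geo$src)[nb, ])^2))
  expect_equal(rep@localizationError[1], want)
})

test_that("pure-noise estimates decorrelate from the true waveforms", {
  geo <- testGeometry()
  scene <- defaultScene(geo$src, seed = 5L)
  sim <- simulateScene(scene, geo$src, geo$G)
  rs <- numeric(20)
  for (k in 1:20) {
    set.seed(1000 + k)
    Jn <- matrix(rnorm(length(sim$Jtrue)), nrow(sim$Jtrue))
    est <- new("SourceEstimate", J = Jn, sfreq = scene@sfreq,
               t0 = scene@epochSpan[1],
               windowBoundaries = c(0L, ncol(Jn)), method = "spatiotemporal")
    rep <- evaluateEstimate(est, sim$Jtrue, scene, geo$src)
    rs[k] <- mean(abs(rep@timecourseCorr))
  }
  expect_lt(mean(rs), 0.2)
})

test_that("patch recovery stays within two mesh edges at 10 dB SNR", {
  geo <- testGeometry()
  edge <- meshEdgeLength(geo$src)
  ok <- 0L; nSeeds <- 12L
  for (seed in seq_len(nSeeds)) {
    scene <- defaultScene(geo$src, snrDb = 10, seed = seed)
    sim <- simulateScene(scene, geo$src, geo$G)
    thr <- thresholdMap(sim$map, geo$src)
    priors <- partitionSubmaps(thr, geo$src)
    est <- fitSpatiotemporal(sim$epochs, geo$G, priors)
    rep <- evaluateEstimate(est, sim$Jtrue, scene, geo$src)
    if (all(rep@localizationError <= 2 * edge)) ok <- ok + 1L
  }
  expect_gte(ok / nSeeds, 0.9)
})

test_that("spatiotemporal priors suppress a spurious fMRI patch", {
  geo <- testGeometry()
  nSeeds <- 10L
  eST <- eTI <- numeric(nSeeds)
  for (seed in seq_len(nSeeds)) {
    scene <- defaultScene(geo$src, seed = 100L + seed, spurious = TRUE)
    sim <- simulateScene(scene, geo$src, geo$G)
    spur <- scene@spuriousPatches[[1]]
    thr <- thresholdMap(sim$map, geo$src)
    priors <- partitionSubmaps(thr, geo$src)
    st <- fitSpatiotemporal(sim$epochs, geo$G, priors)
    ti <- fitTimeInvariant(sim$epochs, geo$G, thr, scoreEvidence = FALSE)
    eST[seed] <- sum(currentDensity(st)[spur, ]^2) /
      sum(currentDensity(st)^2)
    eTI[seed] <- sum(currentDensity(ti)[spur, ]^2) /
      sum(currentDensity(ti)^2)
  }
  expect_lt(mean(eST), mean(eTI))
})

test_that("identical window sizes give perfectly correlated time courses", {
  geo <- testGeometry()
  scene <- defaultScene(geo$src, seed = 2L)
  tab <- windowStabilityExperiment(scene, geo$src, geo$G,
                                   windowSizes = c(40, 40))
  expect_equal(tab$r, c(1, 1), tolerance = 1e-12)
})
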