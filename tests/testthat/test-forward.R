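test_that("icosphere vertex counts follow 10*4^k + 2 and normals are unit", {
  for (k in 0:2) {
    src <- makeIcosphereSourceSpace(k, 0.08)
    expect_identical(nSources(src), as.integer(10 * 4^k + 2))
    # cross-check: vertices are unique points on the sphere
    expect_identical(nrow(unique(round(vertices(src), 12))), nSources(src))
    expect_lt(max(abs(sqrt(rowSums(normals(src)^2)) - 1)), 1e-9)
    expect_equal(sqrt(rowSums(vertices(src)^2)), rep(0.08, nSources(src)))
  }
  # edge count of a closed triangulation: 30 * 4^k
  src <- makeIcosphereSourceSpace(1, 0.08)
  nEdges <- sum(lengths(adjacency(src))) / 2
  expect_equal(nEdges, 30 * 4)
})

test_that("homogeneous-sphere potentials match the closed-form oracle", {
  R <- 0.1; sigma <- 0.33
  hm <- new("SphericalHeadModel", radii = c(0.04, 0.07, R),
            conductivities = rep(sigma, 3), nTerms = 200L)
  el <- electrodeCap(24, R, coverage = 0.9)
  for (b in c(0.005, 0.015, 0.03)) {
    pos <- matrix(c(0, 0, b), 1)
    mom <- matrix(c(0, 0, 1), 1)  # radial
    got <- drop(sphericalPotential(hm, el, pos, mom))
    cosG <- drop((el / R) %*% c(0, 0, 1))
    want <- homRadialPotential(R, sigma, b, cosG)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("a centre dipole produces an antisymmetric topography", {
  hm <- sphericalHeadModel()
  R <- hm@radii[3]
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  equator <- R * cbind(cos(th), sin(th), 0)
  v <- sphericalPotential(hm, equator, matrix(0, 1, 3), matrix(c(0, 0, 1), 1))
  expect_lt(max(abs(v)), 1e-12)          # z-dipole: equatorial plane is at 0
  poles <- R * rbind(c(0, 0, 1), c(0, 0, -1))
  vp <- drop(sphericalPotential(hm, poles, matrix(0, 1, 3),
                                matrix(c(0, 0, 1), 1)))
  expect_equal(vp[1], -vp[2])
  expect_gt(abs(vp[1]), 0)
})

test_that("radial and tangential eccentric dipoles differ as expected", {
  hm <- sphericalHeadModel(nTerms = 200L)
  el <- electrodeCap(48, 0.1, coverage = 0.95)
  pos <- matrix(c(0, 0, 0.06), 1)
  vr <- drop(sphericalPotential(hm, el, pos, matrix(c(0, 0, 1), 1)))
  vt <- drop(sphericalPotential(hm, el, pos, matrix(c(1, 0, 0), 1)))
  expect_gt(max(abs(vr - vt)), 0.1 * max(abs(vr)))  # distinct topographies
  nearest <- which.max(el[, 3])                      # electrode above dipole
  expect_gt(abs(vr[nearest]), abs(vt[nearest]))
})

test_that("average-referenced lead-field columns sum to zero", {
  geo <- testGeometry()
  cs <- colSums(gainMatrix(geo$G))
  expect_lt(max(abs(cs)), 1e-10)
})

test_that("series increments shrink monotonically with truncation order", {
  hm <- sphericalHeadModel()
  el <- electrodeCap(8, 0.1)
  pos <- matrix(c(0.02, 0, 0.05), 1)
  mom <- matrix(c(0, 0, 1), 1)
  orders <- c(10L, 20L, 40L, 80L)
  Gs <- lapply(orders, function(n)
    suppressWarnings(sphericalPotential(hm, el, pos, mom, nTerms = n)))
  incr <- vapply(seq_len(3), function(i) max(abs(Gs[[i + 1]] - Gs[[i]])), 1)
  expect_true(all(diff(incr) < 0))
})

test_that("sources outside the innermost shell are rejected by vertex", {
  hm <- sphericalHeadModel()
  el <- electrodeCap(8, 0.1)
  pos <- rbind(c(0, 0, 0.05), c(0, 0, 0.09))  # second outside 0.087
  expect_error(sphericalPotential(hm, el, pos, matrix(0:1, 2, 3)),
               "vertex 2")
  expect_error(sphericalPotential(hm, el * 0.5, matrix(c(0, 0, 0.05), 1),
                                  matrix(c(0, 0, 1), 1)),
               "outside the outer shell")
})

test_that("mesh patches grow by adjacency rings", {
  src <- makeIcosphereSourceSpace(1, 0.07)
  p0 <- meshPatch(src, 1L, 0L)
  expect_identical(p0, 1L)
  p1 <- meshPatch(src, 1L, 1L)
  expect_setequal(p1, sort(c(1L, adjacency(src)[[1]])))
  expect_true(all(meshPatch(src, 1L, 1L) %in% meshPatch(src, 1L, 2L)))
})
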