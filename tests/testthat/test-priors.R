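test_that("GLM t-map handles degenerate, antisymmetric and null cases", {
  set.seed(31)
  Tn <- 60
  des <- glmDesign(Tn, tr = 2, onsets = list(seq(10, 100, by = 30)),
                   durations = 10)
  cvec <- c(1, 0)
  # zero-residual vertex: response equals the regressor exactly
  bold <- cbind(des$X[, 1], des$X[, 1] + rnorm(Tn, sd = 0.5))
  expect_warning(tv <- glmTmap(bold, des, cvec), "capped")
  expect_identical(as.numeric(tv[1]), 1e6)
  # sign-flipped contrast negates t exactly
  t1 <- suppressWarnings(glmTmap(bold, des, cvec))
  t2 <- suppressWarnings(glmTmap(bold, des, -cvec))
  expect_identical(as.numeric(t1), -as.numeric(t2))
  expect_identical(attr(t1, "dof"), 58L)
})

test_that("pure-noise t-maps have a calibrated type-I error rate", {
  set.seed(32)
  Tn <- 40
  des <- glmDesign(Tn, tr = 2, onsets = list(c(6, 30, 54)), durations = 8)
  bold <- matrix(rnorm(Tn * 1000), Tn)
  tv <- glmTmap(bold, des, c(1, 0))
  crit <- qt(0.975, df = attr(tv, "dof"))
  rate <- mean(abs(tv) > crit)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("rank-deficient designs are refused with the offending columns", {
  X <- cbind(a = rep(1, 10), b = 1:10, c = 2 * (1:10))
  expect_error(glmTmap(matrix(rnorm(10), 10, 1), X, c(1, 0, 0)),
               "collinear")
})

test_that("cluster-extent thresholding keeps the 6-patch, drops the 3-patch", {
  src <- chainSourceSpace(30)
  stat <- numeric(30)
  patch6 <- 3:8; patch3 <- 15:17
  stat[c(patch6, patch3)] <- 10
  map <- activationMap(stat, dof = 100)
  thr <- thresholdMap(map, src, p = 0.05, minCluster = 4L)
  expect_identical(nClusters(thr), 1L)
  expect_identical(which(clusterLabels(thr) > 0L), patch6)
  # brute-force components oracle on the suprathreshold set
  surv <- which(2 * pt(10, 100, lower.tail = FALSE) < 0.05 & stat == 10)
  oracle <- bfComponents(surv, adjacency(src))
  oracleSizes <- sort(as.integer(table(oracle)), decreasing = TRUE)
  expect_identical(oracleSizes, c(6L, 3L))
  # inclusive boundary: a cluster of exactly minCluster survives
  thr3 <- thresholdMap(map, src, p = 0.05, minCluster = 3L)
  expect_identical(nClusters(thr3), 2L)
})

test_that("thresholding is monotone in p and cluster extent", {
  src <- makeIcosphereSourceSpace(1, 0.07)
  s <- nSources(src)
  for (seed in 1:5) {
    set.seed(seed)
    map <- activationMap(rnorm(s, sd = 3), dof = 40)
    base <- thresholdMap(map, src, p = 0.05, minCluster = 2L)
    nBase <- sum(clusterLabels(base) > 0)
    stricterP <- thresholdMap(map, src, p = 0.01, minCluster = 2L)
    stricterK <- thresholdMap(map, src, p = 0.05, minCluster = 4L)
    expect_lte(sum(clusterLabels(stricterP) > 0), nBase)
    expect_lte(sum(clusterLabels(stricterK) > 0), nBase)
    expect_true(all(which(clusterLabels(stricterP) > 0) %in%
                      which(clusterLabels(base) > 0)))
    expect_true(all(which(clusterLabels(stricterK) > 0) %in%
                      which(clusterLabels(base) > 0)))
  }
})

test_that("cluster partitioning matches the brute-force oracle and covers", {
  src <- makeIcosphereSourceSpace(1, 0.07)
  set.seed(33)
  map <- activationMap(rnorm(nSources(src), sd = 3), dof = 40)
  thr <- thresholdMap(map, src, p = 0.1, minCluster = 2L)
  priors <- partitionSubmaps(thr, src, mode = "clusters")
  surviving <- which(clusterLabels(thr) > 0)
  all_idx <- sort(unlist(submaps(priors)))
  expect_identical(all_idx, surviving)                 # covering
  expect_identical(anyDuplicated(unlist(submaps(priors))), 0L)  # disjoint
  oracle <- bfComponents(surviving, adjacency(src))
  for (sm in submaps(priors)) {
    labs <- unique(oracle[as.character(sm)])
    expect_length(labs, 1L)                            # submap = one component
    expect_identical(sort(as.integer(names(oracle)[oracle == labs])), sm)
  }
})

test_that("label mode splits clusters by region and requires labels", {
  src <- chainSourceSpace(10)
  stat <- c(rep(10, 6), rep(0, 4))
  map <- thresholdMap(activationMap(stat, dof = 100), src, p = 0.05,
                      minCluster = 2L)
  expect_error(partitionSubmaps(map, src, mode = "labels"), "region labels")
  regionLabels(src) <- rep(c("A", "B"), each = 5)
  pr <- partitionSubmaps(map, src, mode = "labels")
  expect_identical(nComponents(pr), 2L)
  expect_setequal(submaps(pr)[[1]], 1:5)
  expect_setequal(submaps(pr)[[2]], 6L)
})

test_that("empty threshold yields an empty prior set", {
  src <- chainSourceSpace(8)
  thr <- thresholdMap(activationMap(numeric(8), dof = 50), src)
  pr <- partitionSubmaps(thr, src)
  expect_identical(nComponents(pr), 0L)
})

test_that("covariance components match the literal rank-1 and diagonal forms", {
  pr <- buildComponents(list(c(1L, 2L)), 3, encoding = "indicator-rank1")
  Q <- as.matrix(componentMatrix(pr, 1))
  expect_equal(Q, rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 0)),
               ignore_attr = TRUE)
  prD <- buildComponents(list(c(1L, 2L)), 3, encoding = "diagonal")
  expect_equal(as.matrix(componentMatrix(prD, 1)), diag(c(1, 1, 0)),
               ignore_attr = TRUE)
  expect_error(buildComponents(list(1:3, 3:5), 6), "overlap")
  # PSD: eigenvalues of every component are >= -1e-12
  set.seed(34)
  prR <- buildComponents(list(c(2L, 5L, 7L), c(1L, 9L)), 10)
  for (i in 1:2) {
    ev <- eigen(as.matrix(componentMatrix(prR, i)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
  }
  # unit-weight sum is PSD with support equal to the union
  R <- as.matrix(assembleR(prR, weights = c(1, 1)))
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  expect_setequal(which(rowSums(abs(R)) > 0), c(1L, 2L, 5L, 7L, 9L))
})
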