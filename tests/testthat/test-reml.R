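test_that("sensor components are the projected priors plus noise", {
  set.seed(41)
  m <- 6; s <- 15
  G <- matrix(rnorm(m * s), m, s)
  noise <- identityNoise(m)
  # N = 0: only C
  empty <- buildComponents(list(), s)
  expect_identical(sensorCovarianceComponents(G, empty, noise), list(diag(m)))
  # singleton rank-1 submap: outer product of one gain column
  pr1 <- buildComponents(list(4L), s)
  comps <- sensorCovarianceComponents(G, pr1, noise)
  expect_equal(comps[[2]], tcrossprod(G[, 4]))
  # dense triple-product oracle, both encodings
  for (enc in c("indicator-rank1", "diagonal")) {
    pr <- buildComponents(list(c(2L, 9L, 11L), c(5L, 6L)), s, encoding = enc)
    comps <- sensorCovarianceComponents(G, pr, noise)
    for (i in 1:2) {
      Qd <- as.matrix(componentMatrix(pr, i))
      expect_lt(max(abs(comps[[i + 1]] - G %*% Qd %*% t(G))), 1e-12)
    }
  }
  expect_error(sensorCovarianceComponents(G, pr1, diag(m + 1)), "rows")
})

test_that("free energy reproduces the Gaussian log-density and prior penalty", {
  hyper <- hyperPrior()
  # m = 1, d = 1, Sigma = 1, Y = 0: data terms are the standard normal
  # log-density at zero
  f <- freeEnergy(matrix(0, 1, 1), list(matrix(1, 1, 1)), lambda = 0,
                  hyper = hyperPrior(eta = 0, pi = 256))
  bd <- attr(f, "breakdown")
  expect_equal(unname(bd["data"]), -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(unname(bd["prior"]), 0)
  # quadratic prior penalty: moving lambda delta off the prior mean costs
  # delta^2 / (2 * priorVariance), data terms untouched
  delta <- 0.7
  f0 <- freeEnergy(matrix(0, 1, 1), list(matrix(1, 1, 1)), 0,
                   hyperPrior(eta = 0, pi = 4))
  f1 <- freeEnergy(matrix(0, 1, 1), list(matrix(1, 1, 1)), 0,
                   hyperPrior(eta = -delta, pi = 4))
  expect_equal(as.numeric(f0 - f1), delta^2 / (2 * 4), tolerance = 1e-12)
})

test_that("free energy matches a term-by-term independent evaluation", {
  set.seed(42)
  m <- 3; d <- 7
  comps <- list(diag(m), randomPSD(m), randomPSD(m, rank = 1))
  lam <- c(0.3, -0.8, 0.5)
  Y <- matrix(rnorm(m * d), m, d)
  hyper <- hyperPrior(eta = -2, pi = 9)
  got <- as.numeric(freeEnergy(Y, comps, lam, hyper))
  # oracle: explicit per-sample Gaussian log-density via eigendecomposition
  Sig <- exp(lam[1]) * comps[[1]] + exp(lam[2]) * comps[[2]] +
    exp(lam[3]) * comps[[3]]
  ee <- eigen(Sig, symmetric = TRUE)
  logdet <- sum(log(ee$values))
  quad <- sum(vapply(seq_len(d), function(j) {
    z <- crossprod(ee$vectors, Y[, j])
    sum(z^2 / ee$values)
  }, 1))
  ll <- -0.5 * quad - 0.5 * d * logdet - 0.5 * d * m * log(2 * pi)
  want <- ll - 0.5 * sum((lam - hyper@eta)^2) / hyper@pi
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(freeEnergy(Y, comps, c(-800, -800, -800), hyper),
               "positive definite")
})

test_that("the default hyperprior is the (-32, 256) log-scale shrinkage prior", {
  hp <- hyperPrior()
  expect_identical(hp@eta, -32)
  expect_identical(hp@pi, 256)
  expect_error(hyperPrior(pi = -1), "positive")
})

test_that("ReML recovers the generating component and shuts the other off", {
  set.seed(43)
  m <- 10; s <- 24; d <- 80
  G <- matrix(rnorm(m * s), m, s)
  pr <- buildComponents(list(1L:4L, 13L:16L), s)
  noise <- identityNoise(m)
  comps <- sensorCovarianceComponents(G, pr, noise)
  # data generated from component 1 only (coherent patch activity)
  q1 <- numeric(s); q1[1:4] <- 1
  J <- q1 %o% rnorm(d, sd = 8)
  Y <- G %*% J + matrix(rnorm(m * d), m, d)
  fit <- remlEstimate(Y, comps, priors = pr)
  expect_true(fit@converged)
  w <- componentWeights(fit)
  # under the weak (sd = 16) log-scale shrinkage prior an unsupported
  # component settles where the prior pull balances sampling fluctuation;
  # three orders of magnitude below the generating component in practice
  expect_gt(w[2] / w[3], 1e3)
  expect_lt(w[3] / w[2], 1e-3)
  # assembled R is dominated by the generating submap
  R <- as.matrix(sourceCovariance(fit))
  expect_gt(max(abs(R[1:4, 1:4])), 1e-6)
  expect_lt(max(abs(R[13:16, 13:16])), 1e-2 * max(abs(R)))
})

test_that("ReML matches an exhaustive grid search on 2-hyperparameter toys", {
  set.seed(44)
  for (rep in 1:3) {
    m <- 2; d <- 400
    K1 <- randomPSD(m, rank = 1)    # rank-1: well-identified against I
    K1 <- K1 * (m / sum(diag(K1)))
    comps <- list(diag(m), K1)
    lamTrue <- c(runif(1, -1, 1), runif(1, -1, 1))
    Sig <- exp(lamTrue[1]) * comps[[1]] + exp(lamTrue[2]) * comps[[2]]
    Y <- t(chol(Sig)) %*% matrix(rnorm(m * d), m, d)
    hyper <- hyperPrior()
    fit <- remlEstimate(Y, comps, hyper = hyper, scale = "none", tol = 1e-8)
    gs <- gridSearchLambda(Y, comps, hyper, lo = -4, hi = 3, nGrid = 71)
    expect_lt(max(abs(muLambda(fit) - gs$lambda)), gs$step + 1e-9)
  }
})

test_that("the free-energy trace never decreases", {
  set.seed(45)
  for (rep in 1:20) {
    m <- sample(3:12, 1)
    p <- sample(2:5, 1)
    d <- sample(c(5, 20, 60), 1)
    comps <- c(list(diag(m)),
               replicate(p - 1, randomPSD(m, rank = sample(1:m, 1)),
                         simplify = FALSE))
    Y <- matrix(rnorm(m * d, sd = runif(1, 0.5, 4)), m, d)
    fit <- suppressWarnings(remlEstimate(Y, comps))
    expect_gte(min(diff(freeEnergyTrace(fit))), 0)
  }
})

test_that("source components shrink toward 'off' when data are pure noise", {
  set.seed(46)
  m <- 8; s <- 20; d <- 100
  G <- matrix(rnorm(m * s), m, s)
  pr <- buildComponents(list(2L:5L, 11L:14L), s)
  comps <- sensorCovarianceComponents(G, pr, identityNoise(m))
  Y <- matrix(rnorm(m * d), m, d)   # noise only, unit variance
  fit <- remlEstimate(Y, comps, priors = pr)
  w <- componentWeights(fit)
  expect_lt(max(w[2:3]) / w[1], 0.1)
})

test_that("adding a null component costs little evidence on average (Occam)", {
  set.seed(47)
  m <- 6; d <- 60
  dF <- numeric(20)
  for (rep in 1:20) {
    K1 <- randomPSD(m)
    K1 <- K1 * (m / sum(diag(K1)))
    Knull <- randomPSD(m, rank = 2)
    Knull <- Knull * (m / sum(diag(Knull)))
    Sig <- diag(m) + 2 * K1
    Y <- t(chol(Sig)) %*% matrix(rnorm(m * d), m, d)
    f2 <- remlEstimate(Y, list(diag(m), K1))
    f3 <- remlEstimate(Y, list(diag(m), K1, Knull))
    dF[rep] <- logEvidence(f3) - logEvidence(f2)
  }
  expect_lt(mean(dF), 0.5)
})

test_that("the inverse solution is exact in its algebraic limits", {
  set.seed(48)
  # Y = 0 -> J = 0
  G <- matrix(rnorm(16), 4, 4)
  J0 <- inverseSolution(matrix(0, 4, 3), G, diag(4), diag(4), 1)
  expect_identical(max(abs(J0)), 0)
  # R = I, C = I, lambda -> 0, square invertible G: J -> G^-1 Y
  Y <- matrix(rnorm(8), 4, 2)
  J <- inverseSolution(Y, G, diag(4), diag(4), 1e-12)
  expect_equal(as.matrix(J), solve(G, Y), tolerance = 1e-8)
})

test_that("the inverse solution agrees with its Woodbury dual form", {
  set.seed(49)
  for (rep in 1:10) {
    m <- 4; s <- 6; d <- 5
    G <- matrix(rnorm(m * s), m, s)
    R <- randomPSD(s) + diag(s) * 0.5
    C <- randomPSD(m) + diag(m) * 0.5
    lam <- runif(1, 0.05, 2)
    Y <- matrix(rnorm(m * d), m, d)
    J1 <- inverseSolution(Y, G, R, C, lam)
    Cli <- solve(lam * C)
    J2 <- solve(t(G) %*% Cli %*% G + solve(R), t(G) %*% Cli %*% Y)
    expect_equal(as.matrix(J1), J2, tolerance = 1e-8)
  }
})

test_that("assembleR obeys shutoff, scaling and the dense oracle", {
  pr <- buildComponents(list(c(1L, 2L)), 4)
  # prior-mean shutoff: all weights exp(-32) leave R numerically off
  Roff <- assembleR(pr, muLambda = -32)
  expect_lte(max(abs(Roff)), exp(-32))
  # single submap at weight ln 2: the block is 2 * ones
  R2 <- as.matrix(assembleR(pr, muLambda = log(2)))
  expect_equal(R2[1:2, 1:2], matrix(2, 2, 2), ignore_attr = TRUE)
  expect_identical(max(abs(R2[3:4, ])), 0)
  # random weights match the dense sum
  set.seed(50)
  prR <- buildComponents(list(c(1L, 5L, 6L), c(2L, 3L)), 8)
  w <- runif(2)
  want <- w[1] * as.matrix(componentMatrix(prR, 1)) +
    w[2] * as.matrix(componentMatrix(prR, 2))
  expect_lt(max(abs(as.matrix(assembleR(prR, weights = w)) - want)), 1e-12)
  expect_error(assembleR(prR, weights = c(-1, 1)), "negative")
})

test_that("the generating-R inverse beats a mismatched R on squared error", {
  set.seed(51)
  m <- 8; s <- 20; d <- 4
  G <- matrix(rnorm(m * s), m, s)
  pr <- buildComponents(list(3L:6L), s, encoding = "diagonal")
  Rtrue <- as.matrix(assembleR(pr, weights = 25))
  C <- diag(m)
  seTrue <- seMis <- numeric(30)
  for (rep in 1:30) {
    J <- matrix(0, s, d)
    J[3:6, ] <- matrix(rnorm(4 * d, sd = 5), 4, d)
    Y <- G %*% J + matrix(rnorm(m * d), m, d)
    seTrue[rep] <- sum((as.matrix(inverseSolution(Y, G, Rtrue, C, 1)) - J)^2)
    seMis[rep] <- sum((as.matrix(
      inverseSolution(Y, G, diag(s) * 25, C, 1)) - J)^2)
  }
  expect_lt(mean(seTrue), mean(seMis))
})

test_that("degenerate windows (d < m) are accepted", {
  set.seed(52)
  m <- 10; d <- 3
  comps <- list(diag(m), randomPSD(m))
  Y <- matrix(rnorm(m * d), m, d)
  fit <- suppressWarnings(remlEstimate(Y, comps))
  expect_s4_class(fit, "ReMLFit")
  expect_true(all(is.finite(muLambda(fit))))
})

test_that("empty or zero component lists are refused", {
  Y <- matrix(rnorm(8), 4, 2)
  expect_error(remlEstimate(Y, list()), "at least one")
  expect_error(remlEstimate(Y, list(matrix(0, 4, 4))), "zero")
})
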