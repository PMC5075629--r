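#' @include AllClasses.R
NULL

#' HyperPrior constructor
#'
#' @param eta prior mean of each log-scale hyperparameter (default -32,
#'   i.e. components are switched off unless the data support them).
#' @param pi prior variance of each log-scale hyperparameter (default 256).
#' @return a [HyperPrior-class].
#' @export
hyperPrior <- function(eta = -32, pi = 256) {
  new("HyperPrior", eta = eta, pi = pi)
}

#' NoiseModel constructors
#'
#' \code{identityNoise(m)} is the white-noise fallback;
#' \code{baselineNoise(epochs, baselineSpan, shrinkage)} estimates the
#' sensor covariance from a pre-stimulus baseline as a shrinkage-regularised
#' sample covariance (shrinkage toward the scaled identity).
#'
#' @param m number of channels.
#' @return a [NoiseModel-class].
#' @export
identityNoise <- function(m) {
  .newNoiseModel(diag(m), "identity")
}

## the slot is named C, which would partially match new()'s Class formal,
## so NoiseModel is built by slot assignment
.newNoiseModel <- function(C, source) {
  x <- new("NoiseModel")
  x@C <- C
  x@source <- source
  validObject(x)
  x
}

#' @rdname identityNoise
#' @param epochs an [EEGEpochs-class].
#' @param baselineSpan c(t0, t1) seconds of the baseline window (default
#'   the whole pre-stimulus span).
#' @param shrinkage shrinkage weight toward the scaled identity, in [0, 1].
#' @export
baselineNoise <- function(epochs, baselineSpan = NULL, shrinkage = 0.1) {
  stopifnot(is(epochs, "EEGEpochs"))
  d <- nSamples(epochs)
  tt <- epochs@t0 + (seq_len(d) - 1) / epochs@sfreq
  if (is.null(baselineSpan)) baselineSpan <- c(epochs@t0, 0)
  idx <- which(tt >= baselineSpan[1] & tt < baselineSpan[2])
  m <- nChannels(epochs)
  if (length(idx) < 2L) {
    warning("baseline span too short; falling back to identity noise")
    return(identityNoise(m))
  }
  X <- NULL
  for (e in seq_len(nEpochs(epochs)))
    X <- cbind(X, matrix(epochs@data[e, , idx], m))
  X <- X - rowMeans(X)
  S <- tcrossprod(X) / ncol(X)
  S <- (S + t(S)) / 2
  C <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(m)
  .newNoiseModel(C, "baseline-estimated")
}

#' Sensor-space covariance components
#'
#' Projects the source covariance components into sensor space: returns
#' the list {C, G Q_1 G', ..., G Q_N G'} whose exp-weighted sum is the
#' model covariance Sigma(lambda) = G R G' + lambda^C C. Under the
#' indicator-rank1 encoding G Q_i G' is the outer product of the summed
#' gain columns of the submap.
#'
#' @param G a [LeadField-class] or plain m x s gain matrix.
#' @param priors a [PriorSet-class] (may be empty: only C is returned).
#' @param noise a [NoiseModel-class] or plain m x m matrix.
#' @return list of m x m symmetric components; the noise covariance is
#'   always element 1.
#' @export
sensorCovarianceComponents <- function(G, priors, noise) {
  if (is(G, "LeadField")) G <- gainMatrix(G)
  C <- if (is(noise, "NoiseModel")) noise@C else as.matrix(noise)
  if (nrow(C) != nrow(G))
    stop(sprintf("noise covariance is %dx%d but the gain matrix has %d rows",
                 nrow(C), ncol(C), nrow(G)))
  comps <- list(C)
  if (!is.null(priors) && nComponents(priors) > 0) {
    if (nSources(priors) != ncol(G))
      stop(sprintf("priors span %d sources but the gain matrix has %d columns",
                   nSources(priors), ncol(G)))
    for (i in seq_len(nComponents(priors))) {
      q <- priors@submaps[[i]]
      Gi <- G[, q, drop = FALSE]
      K <- if (priors@encoding == "indicator-rank1") {
        g <- rowSums(Gi)
        tcrossprod(g)
      } else {
        tcrossprod(Gi)
      }
      comps[[i + 1L]] <- (K + t(K)) / 2
    }
  }
  comps
}

## Sigma(lambda) = sum_i exp(lambda_i) K_i; returns NULL if not PD
.sigma_chol <- function(components, lambda) {
  Sig <- 0
  for (i in seq_along(components))
    Sig <- Sig + exp(lambda[i]) * components[[i]]
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  list(Sigma = Sig, chol = ch)
}

#' Variational free energy of one window
#'
#' Evaluates, for EEG window data Y (m x d) under the covariance-component
#' model Sigma(lambda) = sum_i exp(lambda_i) K_i,
#' \deqn{F = -\frac{d}{2}\mathrm{tr}(\Sigma^{-1}S) - \frac{d}{2}\ln|\Sigma|
#'   - \frac{dm}{2}\ln 2\pi - \frac{1}{2}(\lambda-\eta)'\Pi(\lambda-\eta)
#'   \; [+ \tfrac{1}{2}\ln|\Sigma^\lambda \Pi|],}
#' with S = YY'/d and Pi the hyperprior precision matrix (I / pi). The
#' bracketed posterior-entropy term is included only when a hyperparameter
#' posterior covariance \code{sigmaLambda} is supplied (as in the final
#' evidence reported by [remlEstimate()]); without it the value is the
#' ReML ascent objective. Deterministic in its inputs.
#'
#' @param Y m x d window data (microvolts), or an m x m second-moment
#'   matrix S with \code{d} given explicitly.
#' @param components list of m x m covariance components (noise first).
#' @param lambda numeric vector of log-scale weights, one per component.
#' @param hyper a [HyperPrior-class].
#' @param sigmaLambda optional posterior covariance of lambda.
#' @param d number of samples (defaults to ncol(Y)).
#' @return scalar F with attribute \code{"breakdown"} (data, prior,
#'   entropy terms).
#' @export
freeEnergy <- function(Y, components, lambda, hyper = hyperPrior(),
                       sigmaLambda = NULL, d = NULL) {
  m <- nrow(components[[1]])
  if (is.null(d)) {
    d <- ncol(Y)
    S <- tcrossprod(Y) / d
  } else {
    S <- Y  # caller passed the second-moment matrix directly
  }
  stopifnot(length(lambda) == length(components))
  sc <- .sigma_chol(components, lambda)
  if (is.null(sc$chol))
    stop("Sigma(lambda) is not positive definite at the supplied lambda")
  logdet <- 2 * sum(log(diag(sc$chol)))
  trSinv <- sum(chol2inv(sc$chol) * S)   # tr(Sigma^-1 S), both symmetric
  dataTerm <- -0.5 * d * (trSinv + logdet + m * log(2 * pi))
  dev <- lambda - hyper@eta
  priorTerm <- -0.5 * sum(dev^2) / hyper@pi
  entropyTerm <- 0
  if (!is.null(sigmaLambda)) {
    p <- length(lambda)
    entropyTerm <- 0.5 * (determinant(sigmaLambda, logarithm = TRUE)$modulus[1] -
                            p * log(hyper@pi))
  }
  structure(dataTerm + priorTerm + entropyTerm,
            breakdown = c(data = dataTerm, prior = priorTerm,
                          entropy = entropyTerm))
}

#' ReML estimation of covariance-component weights
#'
#' Maximises the free energy over the log-scale component weights by
#' Fisher scoring with step-halving, which guarantees a non-decreasing
#' objective trace. By default every component and the data second moment
#' are trace-normalised internally (mean diagonal 1) so that the
#' hyperprior's "off" level (eta = -32) and "on" level (lambda ~ 0) are
#' meaningful regardless of physical units; the returned \code{weights}
#' are the effective linear multipliers of the components in their
#' original units, and \code{R} (when \code{priors} is given) is the
#' assembled source covariance \code{sum_i weights[i+1] * Q_i}.
#'
#' @param Y m x d window data.
#' @param components list of m x m sensor covariance components, the noise
#'   covariance first (see [sensorCovarianceComponents()]).
#' @param hyper a [HyperPrior-class]; default eta = -32, pi = 256.
#' @param priors optional [PriorSet-class] whose submaps correspond to
#'   components 2..N+1; used to assemble the source covariance R.
#' @param scale "auto" (trace-normalise, default) or "none" (optimise the
#'   raw objective of [freeEnergy()] directly).
#' @param tol convergence tolerance on the objective increase (default 1e-4).
#' @param maxIter maximum Fisher-scoring iterations (default 128).
#' @param lambdaInit optional initial lambda (in the scaled convention).
#' @return a [ReMLFit-class].
#' @export
remlEstimate <- function(Y, components, hyper = hyperPrior(),
                         priors = NULL, scale = c("auto", "none"),
                         tol = 1e-4, maxIter = 128L, lambdaInit = NULL) {
  scale <- match.arg(scale)
  p <- length(components)
  if (p < 1L) stop("need at least one covariance component")
  m <- nrow(components[[1]])
  d <- ncol(Y)
  if (d < 1L) stop("window must contain at least one sample")
  if (nrow(Y) != m) stop("Y and components disagree on channel count")
  components <- lapply(components, function(K) (as.matrix(K) + t(as.matrix(K))) / 2)
  if (all(vapply(components, function(K) max(abs(K)), 1) < .Machine$double.eps))
    stop("all covariance components are numerically zero")
  S <- tcrossprod(Y) / d
  if (scale == "auto") {
    sY <- m / max(sum(diag(S)), .Machine$double.xmin)
    sK <- vapply(components, function(K) m / max(sum(diag(K)),
                                                 .Machine$double.xmin), 1)
  } else {
    sY <- 1
    sK <- rep(1, p)
  }
  St <- S * sY
  Kt <- lapply(seq_len(p), function(i) components[[i]] * sK[i])
  lam <- if (is.null(lambdaInit)) rep(0, p) else rep_len(lambdaInit, p)
  piv <- hyper@pi
  eta <- hyper@eta
  objective <- function(l) {
    sc <- .sigma_chol(Kt, l)
    if (is.null(sc$chol)) return(-Inf)
    logdet <- 2 * sum(log(diag(sc$chol)))
    tr <- sum(chol2inv(sc$chol) * St)
    -0.5 * d * (tr + logdet + m * log(2 * pi)) -
      0.5 * sum((l - eta)^2) / piv
  }
  Ftrace <- objective(lam)
  if (!is.finite(Ftrace))
    stop("initial Sigma(lambda) is not positive definite")
  converged <- FALSE
  H <- diag(p)
  for (it in seq_len(maxIter)) {
    sc <- .sigma_chol(Kt, lam)
    Pm <- chol2inv(sc$chol)
    PS <- Pm %*% St
    A <- lapply(seq_len(p), function(i) Pm %*% (exp(lam[i]) * Kt[[i]]))
    g <- vapply(seq_len(p), function(i)
      0.5 * d * (sum(A[[i]] * t(PS)) - sum(diag(A[[i]]))) -
        (lam[i] - eta) / piv, 1)
    for (i in seq_len(p)) for (j in i:p) {
      H[i, j] <- 0.5 * d * sum(A[[i]] * t(A[[j]]))
      H[j, i] <- H[i, j]
    }
    diag(H) <- diag(H) + 1 / piv
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8 * max(diag(H)), p), g))
    Fcur <- Ftrace[length(Ftrace)]
    alpha <- 1
    repeat {
      lamNew <- pmin(pmax(lam + alpha * step, -256), 256)
      Fnew <- objective(lamNew)
      if (Fnew >= Fcur - .Machine$double.eps * abs(Fcur)) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { lamNew <- lam; Fnew <- Fcur; break }
    }
    lam <- lamNew
    Ftrace <- c(Ftrace, max(Fnew, Fcur))
    dF <- Ftrace[length(Ftrace)] - Fcur
    if (abs(dF) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ReML did not converge within ", maxIter, " iterations")
  sigmaLambda <- tryCatch(solve(H), error = function(e)
    diag(piv, p))
  sigmaLambda <- (sigmaLambda + t(sigmaLambda)) / 2
  Ffinal <- Ftrace[length(Ftrace)] +
    0.5 * (determinant(sigmaLambda, logarithm = TRUE)$modulus[1] -
             p * log(piv))
  weights <- exp(lam) * sK / sY
  R <- if (!is.null(priors) && nComponents(priors) > 0) {
    assembleR(priors, weights = weights[-1])
  } else {
    Matrix::Matrix(0, 0, 0)
  }
  new("ReMLFit", muLambda = lam, sigmaLambda = sigmaLambda,
      FTrace = Ftrace, logEvidence = as.numeric(Ffinal),
      weights = weights, R = R, converged = converged,
      nIter = length(Ftrace) - 1L)
}

#' Assemble the source covariance R from component weights
#'
#' R = sum_i w_i Q_i over the prior set's components. Weights may be given
#' directly (linear scale, must be non-negative) or as log-scale
#' hyperparameters via \code{muLambda} (then w_i = exp(muLambda_i)).
#'
#' @param priors a [PriorSet-class].
#' @param weights linear weights, one per component.
#' @param muLambda log-scale hyperparameters (alternative to weights).
#' @return sparse symmetric PSD s x s matrix whose support is the union of
#'   the submaps.
#' @export
assembleR <- function(priors, weights = NULL, muLambda = NULL) {
  stopifnot(is(priors, "PriorSet"))
  N <- nComponents(priors)
  if (is.null(weights)) {
    if (is.null(muLambda)) stop("supply weights or muLambda")
    weights <- exp(muLambda)
  }
  if (length(weights) != N)
    stop(sprintf("%d weights for %d components", length(weights), N))
  if (any(weights < 0))
    stop("negative weight in linear-weight mode")
  s <- nSources(priors)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(N)) {
    q <- priors@submaps[[k]]
    if (priors@encoding == "indicator-rank1") {
      ii <- c(ii, rep(q, each = length(q)))
      jj <- c(jj, rep(q, times = length(q)))
      xx <- c(xx, rep(weights[k], length(q)^2))
    } else {
      ii <- c(ii, q); jj <- c(jj, q)
      xx <- c(xx, rep(weights[k], length(q)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(s, s))
}

#' L2-norm inverse solution
#'
#' The weighted minimum-norm estimate
#' J = R G' (G R G' + lambda^C C)^{-1} Y, linear in Y. If the sensor-space
#' system fails to factorise, a jitter of 1e-10 * trace/m is added to its
#' diagonal once (with a message); if it still fails, an error reports the
#' condition estimate.
#'
#' @param Y m x d data (microvolts).
#' @param G a [LeadField-class] or m x s gain matrix.
#' @param R s x s source covariance (sparse or dense).
#' @param C m x m noise covariance.
#' @param lambdaC regularisation weight on C.
#' @return s x d matrix of current densities (nA m).
#' @export
inverseSolution <- function(Y, G, R, C, lambdaC) {
  if (is(G, "LeadField")) G <- gainMatrix(G)
  if (is(C, "NoiseModel")) C <- C@C
  m <- nrow(G)
  stopifnot(nrow(Y) == m, nrow(C) == m)
  RG <- as.matrix(R %*% Matrix::t(Matrix::Matrix(G)))   # s x m
  M <- G %*% RG + lambdaC * C
  M <- (M + t(M)) / 2
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-10 * sum(diag(M)) / m
    message("inverseSolution: adding diagonal jitter ", signif(jit, 3))
    M <- M + diag(jit, m)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch))
      stop("sensor-space system is singular after jitter (rcond = ",
           signif(rcond(M), 3), ")")
  }
  RG %*% chol2inv(ch) %*% Y
}
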