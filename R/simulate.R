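#' @include AllClasses.R
NULL

#' SimScene constructor
#'
#' @param patches list of patch descriptions; each a list with
#'   \code{vertices} (1-based indices), \code{onsetMs}, \code{offsetMs},
#'   \code{amplitude} (nA m, default 20), \code{waveform}
#'   ("gaussian-burst" default, or "boxcar") and optional \code{name}.
#' @param spuriousPatches list of vertex vectors that are fMRI-active but
#'   electrically silent (EEG-fMRI mismatch).
#' @param snrDb sensor SNR over the active span, dB (default 10).
#' @param epochSpan c(t_start, t_end) seconds (default -0.4 .. 1.2).
#' @param sfreq sampling rate, Hz (default 1000).
#' @param seed integer seed recorded in all outputs.
#' @return a [SimScene-class].
#' @export
simScene <- function(patches, spuriousPatches = list(), snrDb = 10,
                     epochSpan = c(-0.4, 1.2), sfreq = 1000, seed = 1L) {
  patches <- lapply(patches, function(p) {
    p$amplitude <- p$amplitude %||% 20
    p$waveform <- p$waveform %||% "gaussian-burst"
    p$vertices <- sort(as.integer(p$vertices))
    p
  })
  new("SimScene", patches = patches, spuriousPatches = spuriousPatches,
      snrDb = snrDb, epochSpan = epochSpan, sfreq = sfreq,
      seed = as.integer(seed))
}

#' Default synthetic visual-motor scene
#'
#' Mimics a visual-stimulus / motor-response timeline: a posterior
#' ("visual") patch bursting at 100-175 ms, a "premotor" patch at
#' 370-460 ms and a "motor" patch centred on the 600 ms response time
#' (560-660 ms), all with equal 20 nA m amplitudes, SNR 10 dB. Patch seeds
#' are the mesh vertices nearest three dispersed cortical directions;
#' each patch is a 1-ring neighbourhood. Optionally adds one spurious
#' (fMRI-active, EEG-silent) patch for mismatch experiments.
#'
#' @param src the [SourceSpace-class] the scene lives on.
#' @param snrDb sensor SNR in dB.
#' @param seed integer seed.
#' @param spurious logical: include the spurious patch (default FALSE).
#' @return a [SimScene-class]; patches carry names "visual", "premotor",
#'   "motor" (and "spurious" in the spurious list).
#' @export
defaultScene <- function(src, snrDb = 10, seed = 1L, spurious = FALSE) {
  dirs <- rbind(visual = c(0, -1, 0.1),
                premotor = c(-0.62, 0.5, 0.6),
                motor = c(0.62, 0.5, 0.6),
                spurious = c(0, -0.5, 0.87))  # inside the sensed cap
  dirs <- dirs / sqrt(rowSums(dirs^2))
  v <- vertices(src)
  vhat <- v / sqrt(rowSums(v^2))
  seedOf <- function(dir) which.max(vhat %*% dir)
  mk <- function(name, on, off) list(
    name = name, vertices = meshPatch(src, seedOf(dirs[name, ]), 1L),
    onsetMs = on, offsetMs = off, amplitude = 20,
    waveform = "gaussian-burst")
  patches <- list(mk("visual", 100, 175),
                  mk("premotor", 370, 460),
                  mk("motor", 560, 660))
  spur <- if (spurious)
    list(spurious = meshPatch(src, seedOf(dirs["spurious", ]), 1L))
  else list()
  simScene(patches, spuriousPatches = spur, snrDb = snrDb, seed = seed)
}

.patch_waveform <- function(p, tMs) {
  if (p$waveform == "boxcar") {
    as.numeric(tMs >= p$onsetMs & tMs < p$offsetMs)
  } else {
    mid <- (p$onsetMs + p$offsetMs) / 2
    sd <- (p$offsetMs - p$onsetMs) / 6
    exp(-0.5 * ((tMs - mid) / sd)^2)
  }
}

#' Simulate EEG, fMRI map and ground truth from a scene
#'
#' Builds the true current density from the scene's patch waveforms,
#' projects it through the lead field, adds sensor noise scaled to the
#' requested SNR (signal power over the active span vs noise power), and
#' constructs the static fMRI activation map as the union of all
#' transiently active patches plus any spurious patches (each assigned a
#' fixed suprathreshold t value of 10 on 100 dof, with inactive vertices
#' at 0). Deterministic given the scene seed.
#'
#' @param scene a [SimScene-class].
#' @param src the [SourceSpace-class].
#' @param G the matching [LeadField-class].
#' @param noiseKind "white" (default) or "correlated" (random smooth
#'   spatial covariance, for robustness experiments).
#' @return list with elements \code{epochs} ([EEGEpochs-class], one trial),
#'   \code{map} (unthresholded [ActivationMap-class]), \code{Jtrue}
#'   (s x d true current density, nA m) and \code{scene}.
#' @export
simulateScene <- function(scene, src, G, noiseKind = c("white", "correlated")) {
  noiseKind <- match.arg(noiseKind)
  stopifnot(is(scene, "SimScene"), is(src, "SourceSpace"),
            is(G, "LeadField"))
  validObject(scene)
  s <- nSources(src)
  for (p in c(scene@patches, lapply(scene@spuriousPatches, function(v)
    list(vertices = v, name = "spurious")))) {
    bad <- p$vertices[p$vertices < 1L | p$vertices > s]
    if (length(bad))
      stop("patch vertex outside the source space: ", bad[1])
  }
  sf <- scene@sfreq
  tt <- seq(scene@epochSpan[1], scene@epochSpan[2] - 1 / sf, by = 1 / sf)
  tMs <- tt * 1000
  d <- length(tt)
  Jtrue <- matrix(0, s, d)
  active <- rep(FALSE, d)
  for (p in scene@patches) {
    w <- .patch_waveform(p, tMs)
    Jtrue[p$vertices, ] <- Jtrue[p$vertices, , drop = FALSE] +
      rep(p$amplitude * w, each = length(p$vertices))
    active <- active | (tMs >= p$onsetMs & tMs < p$offsetMs)
  }
  Gm <- gainMatrix(G)
  Ysig <- Gm %*% Jtrue
  m <- nrow(Gm)
  set.seed(scene@seed)
  if (is.finite(scene@snrDb)) {
    Psig <- mean(Ysig[, active, drop = FALSE]^2)
    Pnoise <- Psig / 10^(scene@snrDb / 10)
    if (noiseKind == "white") {
      E <- matrix(stats::rnorm(m * d, sd = sqrt(Pnoise)), m, d)
    } else {
      W <- matrix(stats::rnorm(m * m), m, m)
      Cn <- 0.3 * diag(m) + 0.7 * tcrossprod(W) / m
      Cn <- Cn * (m / sum(diag(Cn)))
      L <- chol(Cn)
      E <- sqrt(Pnoise) * t(L) %*% matrix(stats::rnorm(m * d), m, d)
    }
  } else {
    E <- matrix(0, m, d)
  }
  Y <- Ysig + E
  arr <- array(0, c(1L, m, d))
  arr[1L, , ] <- Y
  epochs <- new("EEGEpochs", data = arr, sfreq = sf,
                t0 = scene@epochSpan[1],
                channelNames = channelNames(G), condition = "simulated")
  stat <- numeric(s)
  for (p in scene@patches) stat[p$vertices] <- 10
  for (v in scene@spuriousPatches) stat[v] <- 10
  map <- new("ActivationMap", stat = stat, statType = "t", dof = 100,
             clusterLabels = integer(0), thresholdState = "unthresholded")
  out <- list(epochs = epochs, map = map, Jtrue = Jtrue, scene = scene)
  attr(out, "seed") <- scene@seed
  out
}

#' Regional mean source time course
#'
#' @param est a [SourceEstimate-class] (or plain s x d matrix).
#' @param vertices 1-based vertex indices of the region.
#' @return numeric vector, mean over the region's vertices per sample.
#' @export
regionTimecourse <- function(est, vertices) {
  J <- if (is(est, "SourceEstimate")) currentDensity(est) else est
  colMeans(J[vertices, , drop = FALSE])
}

#' Evaluate a source estimate against simulated ground truth
#'
#' Per-patch metrics: localisation error (distance from the true peak
#' vertex to the vertex carrying maximal estimated energy over the patch's
#' active span), Pearson correlation between the estimated regional mean
#' time course and the true patch waveform, plus the fraction of total
#' estimated source energy outside the true support.
#'
#' @param est a [SourceEstimate-class].
#' @param Jtrue true s x d current density from [simulateScene()].
#' @param scene the [SimScene-class].
#' @param src the [SourceSpace-class].
#' @return an [EvalReport-class].
#' @export
evaluateEstimate <- function(est, Jtrue, scene, src) {
  stopifnot(is(est, "SourceEstimate"))
  J <- currentDensity(est)
  s <- nrow(Jtrue)
  stopifnot(nrow(J) == s)
  sf <- samplingRate(est)
  off <- round((est@t0 - scene@epochSpan[1]) * sf)
  dEst <- ncol(J)
  trueCols <- off + seq_len(dEst)      # columns of Jtrue aligned with J
  stopifnot(trueCols[length(trueCols)] <= ncol(Jtrue))
  v <- vertices(src)
  tMs <- (est@t0 + (seq_len(dEst) - 1) / sf) * 1000
  nP <- length(scene@patches)
  locErr <- corr <- numeric(nP)
  nms <- character(nP)
  for (k in seq_len(nP)) {
    p <- scene@patches[[k]]
    nms[k] <- p$name %||% sprintf("patch%d", k)
    eTrue <- rowSums(Jtrue[, trueCols, drop = FALSE]^2)
    truePeak <- p$vertices[which.max(eTrue[p$vertices])]
    span <- tMs >= p$onsetMs & tMs < p$offsetMs
    if (!any(span)) span <- rep(TRUE, dEst)
    ePeak <- which.max(rowSums(J[, span, drop = FALSE]^2))
    locErr[k] <- sqrt(sum((v[truePeak, ] - v[ePeak, ])^2))
    tcEst <- regionTimecourse(J, p$vertices)
    tcTrue <- regionTimecourse(Jtrue[, trueCols, drop = FALSE], p$vertices)
    corr[k] <- if (stats::sd(tcEst) > 0 && stats::sd(tcTrue) > 0)
      stats::cor(tcEst, tcTrue) else NA_real_
  }
  support <- which(rowSums(Jtrue^2) > 0)
  etot <- sum(J^2)
  eOut <- if (etot > 0) sum(J[-support, ]^2) / etot else 0
  new("EvalReport", localizationError = locErr, timecourseCorr = corr,
      energyOutsideTruth = eOut, patchNames = nms)
}

#' Window-size stability experiment
#'
#' Runs the spatiotemporal pipeline on one simulated scene at several
#' window lengths and reports, for a designated region, the Pearson
#' correlation of its reconstructed mean time course against the
#' smallest-window reference.
#'
#' @param scene a [SimScene-class].
#' @param src,G source space and lead field.
#' @param windowSizes numeric vector of window lengths in ms (>= 2 values;
#'   the smallest is the reference).
#' @param region vertex indices of the designated region; default the
#'   scene's "premotor" patch (or the second patch).
#' @param noise,hyper passed to [fitSpatiotemporal()].
#' @return data.frame with columns windowMs and r (reference row has
#'   r = 1), plus attribute \code{"fits"} holding the SourceEstimates.
#' @export
windowStabilityExperiment <- function(scene, src, G,
                                      windowSizes = c(40, 80, 160, 320),
                                      region = NULL, noise = NULL,
                                      hyper = hyperPrior()) {
  stopifnot(length(windowSizes) >= 2L)
  windowSizes <- sort(windowSizes)
  sim <- simulateScene(scene, src, G)
  thr <- thresholdMap(sim$map, src, p = 0.05, minCluster = 4L)
  priors <- partitionSubmaps(thr, src, mode = "clusters")
  if (is.null(region)) {
    idx <- which(vapply(scene@patches, function(p)
      identical(p$name, "premotor"), TRUE))
    if (!length(idx)) idx <- min(2L, length(scene@patches))
    region <- scene@patches[[idx]]$vertices
  }
  fits <- lapply(windowSizes, function(w)
    fitSpatiotemporal(sim$epochs, G, priors, noise = noise, hyper = hyper,
                      scheme = windowingScheme(w)))
  ref <- fits[[1]]
  dRef <- nSamples(ref)
  tcRef <- regionTimecourse(ref, region)
  rs <- vapply(seq_along(fits), function(i) {
    dCom <- min(dRef, nSamples(fits[[i]]))
    stats::cor(tcRef[seq_len(dCom)],
               regionTimecourse(fits[[i]], region)[seq_len(dCom)])
  }, 1)
  out <- data.frame(windowMs = windowSizes, r = rs)
  attr(out, "fits") <- fits
  out
}
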