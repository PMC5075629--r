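#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix Matrix sparseMatrix Diagonal
NULL

setClassUnion("MatrixLike", c("matrix", "Matrix"))

#' SourceSpace: cortical source mesh
#'
#' Holds the dipole support of the inverse problem: mesh vertex positions
#' (metres), outward unit normals (the fixed dipole orientations), the
#' triangle faces, the vertex adjacency (shared-edge neighbours) and optional
#' per-vertex region labels. Vertex indices are 1-based inside R; all file
#' formats written or read by the package use 0-based indices.
#'
#' @slot vertices numeric matrix, s x 3, metres.
#' @slot normals numeric matrix, s x 3, unit rows.
#' @slot faces integer matrix, nFaces x 3, 1-based vertex indices.
#' @slot adjacency list of length s; element i is the sorted integer vector
#'   of the neighbours of vertex i.
#' @slot regionLabels character of length s, or length 0 when unlabelled.
#' @export
setClass("SourceSpace",
  representation(
    vertices = "matrix",
    normals = "matrix",
    faces = "matrix",
    adjacency = "list",
    regionLabels = "character"
  ),
  prototype(regionLabels = character(0))
)

setValidity("SourceSpace", function(object) {
  s <- nrow(object@vertices)
  msg <- character(0)
  if (s < 1L) msg <- c(msg, "source space must contain at least one vertex")
  if (!identical(dim(object@normals), dim(object@vertices)))
    msg <- c(msg, "normals must match vertices in shape")
  nn <- sqrt(rowSums(object@normals^2))
  if (length(nn) && max(abs(nn - 1)) > 1e-9)
    msg <- c(msg, "normals must be unit length within 1e-9")
  if (length(object@adjacency) != s)
    msg <- c(msg, "adjacency must have one entry per vertex")
  for (i in seq_len(s)) {
    nb <- object@adjacency[[i]]
    if (any(nb == i)) return(sprintf("adjacency is reflexive at vertex %d", i))
    for (j in nb) if (!(i %in% object@adjacency[[j]]))
      return(sprintf("adjacency not symmetric for pair (%d, %d)", i, j))
  }
  if (length(object@regionLabels) && length(object@regionLabels) != s)
    msg <- c(msg, "regionLabels must have length 0 or one label per vertex")
  if (length(msg)) msg else TRUE
})

#' SphericalHeadModel: concentric-sphere conductor
#'
#' Analytic multilayer spherical volume conductor used by the built-in
#' forward model. Radii are ordered innermost (brain) to outermost (scalp).
#'
#' @slot radii numeric, strictly increasing shell radii in metres.
#' @slot conductivities numeric, one conductivity per shell, S/m.
#' @slot nTerms integer, truncation order of the spherical-harmonic series.
#' @export
setClass("SphericalHeadModel",
  representation(radii = "numeric", conductivities = "numeric",
                 nTerms = "integer"),
  prototype(nTerms = 100L)
)

setValidity("SphericalHeadModel", function(object) {
  msg <- character(0)
  if (length(object@radii) < 1L || any(diff(object@radii) <= 0))
    msg <- c(msg, "radii must be strictly increasing")
  if (length(object@conductivities) != length(object@radii))
    msg <- c(msg, "need one conductivity per shell")
  if (any(object@conductivities <= 0))
    msg <- c(msg, "conductivities must be positive")
  if (object@nTerms < 1L) msg <- c(msg, "nTerms must be >= 1")
  if (length(msg)) msg else TRUE
})

#' LeadField: gain matrix of the forward model
#'
#' The m x s matrix G mapping unit dipole moments (nA m) at the source-space
#' vertices, oriented along the vertex normals, to referenced scalp
#' potentials in microvolts.
#'
#' @slot gain numeric matrix, m channels x s sources, uV/(nA m).
#' @slot channelNames character, length m, unique.
#' @slot sourceSpaceId character scalar linking to the source space used.
#' @export
setClass("LeadField",
  representation(gain = "matrix", channelNames = "character",
                 sourceSpaceId = "character"),
  prototype(sourceSpaceId = "unknown")
)

setValidity("LeadField", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@gain))) msg <- c(msg, "gain must be finite")
  if (length(object@channelNames) != nrow(object@gain))
    msg <- c(msg, "channelNames must match gain rows")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (nrow(object@gain) > 0 && any(rowSums(abs(object@gain)) == 0))
    msg <- c(msg, "gain has an all-zero row (dead channel)")
  if (ncol(object@gain) > 0 && any(colSums(abs(object@gain)) == 0))
    msg <- c(msg, "gain has an all-zero column (invisible source)")
  if (length(msg)) msg else TRUE
})

#' EEGEpochs: epoched multichannel EEG
#'
#' Epoched (or single-segment continuous) EEG in microvolts, stored as an
#' n_epochs x m x d array with the sampling rate and the latency of the
#' first sample relative to stimulus onset.
#'
#' @slot data numeric array, n_epochs x m channels x d samples, microvolts.
#' @slot sfreq sampling rate, Hz.
#' @slot t0 time of the first sample relative to stimulus onset, seconds.
#' @slot channelNames character, length m, unique.
#' @slot condition character, one label per epoch.
#' @export
setClass("EEGEpochs",
  representation(data = "array", sfreq = "numeric", t0 = "numeric",
                 channelNames = "character", condition = "character")
)

setValidity("EEGEpochs", function(object) {
  d <- dim(object@data)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "data must be n_epochs x channels x samples")
  else {
    if (d[2] < 2L) msg <- c(msg, "need at least 2 channels")
    if (d[3] < 1L) msg <- c(msg, "need at least 1 sample")
    if (length(object@channelNames) != d[2])
      msg <- c(msg, "channelNames must match channel count")
    if (length(object@condition) != d[1])
      msg <- c(msg, "condition must have one label per epoch")
  }
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (length(object@sfreq) != 1L || object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a positive scalar")
  if (!all(is.finite(object@data))) msg <- c(msg, "data contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' ActivationMap: per-vertex fMRI statistic with threshold state
#'
#' A per-vertex statistic map on the source mesh, its threshold settings and
#' the connected-cluster labelling produced by [thresholdMap()]. Label 0
#' marks inactive vertices.
#'
#' @slot stat numeric, one statistic per vertex.
#' @slot statType "t" or "p".
#' @slot dof residual degrees of freedom when statType is "t" (NA otherwise).
#' @slot thresholdP significance level applied (NA while unthresholded).
#' @slot minCluster cluster-extent threshold applied (NA while unthresholded).
#' @slot clusterLabels integer per vertex; 0 = inactive.
#' @slot thresholdState "unthresholded" or "thresholded".
#' @export
setClass("ActivationMap",
  representation(stat = "numeric", statType = "character", dof = "numeric",
                 thresholdP = "numeric", minCluster = "numeric",
                 clusterLabels = "integer", thresholdState = "character"),
  prototype(statType = "t", dof = NA_real_, thresholdP = NA_real_,
            minCluster = NA_real_, thresholdState = "unthresholded")
)

setValidity("ActivationMap", function(object) {
  msg <- character(0)
  if (!object@statType %in% c("t", "p"))
    msg <- c(msg, "statType must be 't' or 'p'")
  if (!object@thresholdState %in% c("unthresholded", "thresholded"))
    msg <- c(msg, "bad thresholdState")
  if (object@thresholdState == "thresholded" &&
      length(object@clusterLabels) != length(object@stat))
    msg <- c(msg, "clusterLabels must match stat length once thresholded")
  if (length(msg)) msg else TRUE
})

#' PriorSet: fMRI submaps and their covariance components
#'
#' The N disjoint submaps q_i carved out of a thresholded activation map,
#' together with the encoding under which each submap becomes a source
#' covariance component Q_i. Under the default \code{"indicator-rank1"}
#' encoding Q_i = q_i q_i^T with q_i the 0/1 indicator vector (a rank-1
#' all-ones block); under \code{"diagonal"} Q_i = diag(q_i). Components are
#' stored implicitly via the submap index sets and materialised sparsely on
#' demand by [componentMatrix()].
#'
#' @slot submaps list of non-empty, pairwise disjoint 1-based integer vectors.
#' @slot encoding "indicator-rank1" or "diagonal".
#' @slot sourceCount total number of source vertices s.
#' @export
setClass("PriorSet",
  representation(submaps = "list", encoding = "character",
                 sourceCount = "integer"),
  prototype(encoding = "indicator-rank1")
)

setValidity("PriorSet", function(object) {
  msg <- character(0)
  if (!object@encoding %in% c("indicator-rank1", "diagonal"))
    msg <- c(msg, "encoding must be 'indicator-rank1' or 'diagonal'")
  all_idx <- unlist(object@submaps)
  if (any(vapply(object@submaps, length, 1L) == 0L))
    msg <- c(msg, "submaps must be non-empty")
  if (anyDuplicated(all_idx))
    msg <- c(msg, "submaps must be pairwise disjoint")
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > object@sourceCount))
    msg <- c(msg, "submap indices out of range")
  if (length(msg)) msg else TRUE
})

#' HyperPrior: Gaussian prior on the log-scale hyperparameters
#'
#' Each log-scale component weight lambda_i carries an independent Gaussian
#' prior with mean \code{eta} and variance \code{pi}. The default
#' (eta = -32, pi = 256) shuts a component off (exp(-32) ~ 1e-14) unless the
#' data pull its weight up, at a cost of only ~2 nats to reach lambda = 0 —
#' the weak automatic-relevance shrinkage standard in empirical-Bayes
#' covariance-component estimation.
#'
#' @slot eta prior mean of each log hyperparameter.
#' @slot pi prior variance of each log hyperparameter (> 0).
#' @export
setClass("HyperPrior",
  representation(eta = "numeric", pi = "numeric"),
  prototype(eta = -32, pi = 256)
)

setValidity("HyperPrior", function(object) {
  if (length(object@pi) != 1L || object@pi <= 0) "pi must be a positive scalar"
  else if (length(object@eta) != 1L) "eta must be a scalar"
  else TRUE
})

#' NoiseModel: sensor noise covariance
#'
#' @slot C numeric m x m symmetric PSD sensor covariance (microvolts^2).
#' @slot source how C was obtained: "identity" or "baseline-estimated".
#' @export
setClass("NoiseModel",
  representation(C = "matrix", source = "character"),
  prototype(source = "identity")
)

setValidity("NoiseModel", function(object) {
  msg <- character(0)
  if (nrow(object@C) != ncol(object@C)) msg <- c(msg, "C must be square")
  else if (max(abs(object@C - t(object@C))) > 1e-8 * max(1, max(abs(object@C))))
    msg <- c(msg, "C must be symmetric")
  if (!object@source %in% c("identity", "baseline-estimated"))
    msg <- c(msg, "bad noise source tag")
  if (length(msg)) msg else TRUE
})

#' ReMLFit: hyperparameter posterior for one analysis window
#'
#' Result of restricted-maximum-likelihood (free-energy) estimation of the
#' covariance-component weights for one EEG window: the Gaussian posterior
#' over the log hyperparameters, the free-energy trace of the ascent, the
#' final free energy (evidence bound, including the posterior-entropy term),
#' the effective linear component weights and the assembled source
#' covariance R.
#'
#' @slot muLambda posterior mean of the log hyperparameters; element 1 is
#'   the sensor-noise component, elements 2..N+1 the source components.
#' @slot sigmaLambda posterior covariance of the log hyperparameters.
#' @slot FTrace value of the ReML objective at each iteration (non-decreasing).
#' @slot logEvidence final variational free energy F (evidence lower bound).
#' @slot weights effective linear weights on the original-unit components
#'   (element 1 multiplies the noise covariance C, i.e. lambda^C of the
#'   inverse solution; the rest multiply the Q_i).
#' @slot R assembled source covariance (sparse), source units.
#' @slot converged logical.
#' @slot nIter number of Fisher-scoring iterations used.
#' @export
setClass("ReMLFit",
  representation(muLambda = "numeric", sigmaLambda = "matrix",
                 FTrace = "numeric", logEvidence = "numeric",
                 weights = "numeric", R = "MatrixLike",
                 converged = "logical", nIter = "integer")
)

setValidity("ReMLFit", function(object) {
  msg <- character(0)
  if (length(object@muLambda) != nrow(object@sigmaLambda))
    msg <- c(msg, "muLambda and sigmaLambda disagree in size")
  if (length(object@FTrace) &&
      any(diff(object@FTrace) < -1e-6 * max(1, abs(object@FTrace[1]))))
    msg <- c(msg, "FTrace must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' WindowingScheme: how an epoch is cut into analysis windows
#'
#' Non-overlapping contiguous windows tiling the epoch; a final partial
#' window is dropped (with a warning at segmentation time).
#'
#' @slot windowMs window length, milliseconds.
#' @slot hopMs hop between window starts; equal to windowMs (non-overlapping).
#' @slot epochSpan optional (t_start, t_end) seconds; NA = use full epoch.
#' @export
setClass("WindowingScheme",
  representation(windowMs = "numeric", hopMs = "numeric",
                 epochSpan = "numeric"),
  prototype(epochSpan = c(NA_real_, NA_real_))
)

setValidity("WindowingScheme", function(object) {
  msg <- character(0)
  if (object@windowMs <= 0) msg <- c(msg, "windowMs must be positive")
  if (object@hopMs != object@windowMs)
    msg <- c(msg, "only non-overlapping windows (hopMs == windowMs) are supported")
  if (length(msg)) msg else TRUE
})

#' SourceEstimate: reconstructed current density
#'
#' Source time courses (nA m) with the window segmentation used to produce
#' them and per-window fit summaries.
#'
#' @slot J numeric matrix, s sources x d samples, nA m.
#' @slot sfreq sampling rate, Hz.
#' @slot t0 time of first sample, seconds.
#' @slot windowBoundaries 0-based sample boundaries, length nWindows + 1,
#'   strictly increasing, first 0, last <= d.
#' @slot perWindowFit list of ReMLFit (possibly empty for baseline fits).
#' @slot method "spatiotemporal" or "time_invariant".
#' @slot sourceSpaceId provenance link to the source space.
#' @slot dataHash provenance digest of the data and gain matrix used.
#' @export
setClass("SourceEstimate",
  representation(J = "matrix", sfreq = "numeric", t0 = "numeric",
                 windowBoundaries = "integer", perWindowFit = "list",
                 method = "character", sourceSpaceId = "character",
                 dataHash = "character"),
  prototype(perWindowFit = list(), sourceSpaceId = "unknown",
            dataHash = "")
)

setValidity("SourceEstimate", function(object) {
  msg <- character(0)
  b <- object@windowBoundaries
  if (length(b) < 2L || any(diff(b) <= 0L))
    msg <- c(msg, "windowBoundaries must be strictly increasing, length >= 2")
  else if (b[1] != 0L || b[length(b)] > ncol(object@J))
    msg <- c(msg, "windowBoundaries must start at 0 and end within the data")
  if (!all(is.finite(object@J))) msg <- c(msg, "J must be finite")
  if (!object@method %in% c("spatiotemporal", "time_invariant"))
    msg <- c(msg, "bad method tag")
  if (length(msg)) msg else TRUE
})

#' SimScene: synthetic visual-motor scene description
#'
#' Scripted time-varying cortical source activity plus a static fMRI map.
#' Each patch is a list with elements \code{vertices} (1-based indices),
#' \code{onsetMs}, \code{offsetMs}, \code{amplitude} (nA m),
#' \code{waveform} ("gaussian-burst" or "boxcar") and an optional
#' \code{name}. Spurious patches are fMRI-active but electrically silent,
#' emulating EEG-fMRI mismatch.
#'
#' @slot patches list of patch descriptions.
#' @slot spuriousPatches list of 1-based integer vertex vectors.
#' @slot snrDb sensor signal-to-noise ratio over the active span, dB.
#' @slot epochSpan (t_start, t_end) of the epoch in seconds.
#' @slot sfreq sampling rate of the simulated EEG, Hz.
#' @slot seed integer seed recorded in all outputs.
#' @export
setClass("SimScene",
  representation(patches = "list", spuriousPatches = "list",
                 snrDb = "numeric", epochSpan = "numeric", sfreq = "numeric",
                 seed = "integer"),
  prototype(spuriousPatches = list(), snrDb = 10,
            epochSpan = c(-0.4, 1.2), sfreq = 1000, seed = 1L)
)

setValidity("SimScene", function(object) {
  msg <- character(0)
  for (p in object@patches) {
    if (is.null(p$vertices) || !length(p$vertices))
      msg <- c(msg, "each patch needs vertices")
    if (!is.null(p$amplitude) && p$amplitude <= 0)
      msg <- c(msg, "patch amplitudes must be positive")
    if (!is.null(p$onsetMs) &&
        (p$onsetMs < object@epochSpan[1] * 1000 ||
         p$offsetMs > object@epochSpan[2] * 1000))
      msg <- c(msg, "patch onset/offset outside the epoch span")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' EvalReport: source-estimate quality metrics
#'
#' @slot localizationError metres, true-peak to estimated-peak per patch.
#' @slot timecourseCorr Pearson r per patch (regional mean vs true waveform).
#' @slot energyOutsideTruth fraction of total source energy outside the
#'   true support, in [0, 1].
#' @slot patchNames labels for the per-patch entries.
#' @export
setClass("EvalReport",
  representation(localizationError = "numeric", timecourseCorr = "numeric",
                 energyOutsideTruth = "numeric", patchNames = "character")
)

setValidity("EvalReport", function(object) {
  msg <- character(0)
  ok <- is.na(object@timecourseCorr) |
    (object@timecourseCorr >= -1 - 1e-12 & object@timecourseCorr <= 1 + 1e-12)
  if (!all(ok)) msg <- c(msg, "correlations must lie in [-1, 1]")
  if (any(object@localizationError < 0, na.rm = TRUE))
    msg <- c(msg, "localization error must be >= 0")
  e <- object@energyOutsideTruth
  if (length(e) && (e < -1e-12 || e > 1 + 1e-12))
    msg <- c(msg, "energyOutsideTruth must be a fraction in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MatrixContainer: named matrix with axis semantics
#'
#' Internal plumbing container: a named real matrix whose rows and columns
#' carry a semantic tag ("channels", "sources", "samples", ...). Round-trips
#' bit-exactly through the binary dialect of [writeMatrixContainer()].
#'
#' @slot name container name.
#' @slot values numeric matrix.
#' @slot rowSemantics,colSemantics axis tags.
#' @export
setClass("MatrixContainer",
  representation(name = "character", values = "matrix",
                 rowSemantics = "character", colSemantics = "character"),
  prototype(rowSemantics = "rows", colSemantics = "cols")
)
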