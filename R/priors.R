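#' @include AllClasses.R
NULL

#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF (difference of two gamma densities, peak ~5 s,
#' undershoot ~15 s, undershoot ratio 1/6) sampled at the given times.
#'
#' @param t times in seconds at which to evaluate.
#' @param peakDelay,undershootDelay gamma shape parameters (seconds).
#' @param ratio undershoot amplitude ratio.
#' @return numeric vector, peak-normalised to 1.
#' @export
canonicalHRF <- function(t, peakDelay = 6, undershootDelay = 16,
                         ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peakDelay, rate = 1) -
    ratio * stats::dgamma(t, shape = undershootDelay, rate = 1)
  h[t < 0] <- 0
  if (max(abs(h)) > 0) h <- h / max(h)
  h
}

#' Build a GLM design matrix from condition onsets
#'
#' Boxcar regressors convolved with the canonical HRF, plus an intercept
#' and optional nuisance columns.
#'
#' @param nScans number of volumes.
#' @param tr repetition time, seconds.
#' @param onsets list of numeric onset vectors (seconds), one per condition.
#' @param durations stimulus durations (seconds), recycled over conditions.
#' @param nuisance optional numeric matrix of extra columns.
#' @return list with \code{X} (design matrix, intercept last) and
#'   \code{conditionCols} (indices of the condition regressors).
#' @export
glmDesign <- function(nScans, tr, onsets, durations = 1,
                      nuisance = NULL) {
  durations <- rep_len(durations, length(onsets))
  tgrid <- (seq_len(nScans) - 1) * tr
  hrf_t <- seq(0, 32, by = tr)
  hrf <- canonicalHRF(hrf_t)
  cols <- lapply(seq_along(onsets), function(i) {
    box <- numeric(nScans)
    for (on in onsets[[i]]) {
      idx <- which(tgrid >= on & tgrid < on + durations[i])
      box[idx] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(nScans)]
    conv
  })
  X <- do.call(cbind, cols)
  colnames(X) <- sprintf("cond%d", seq_along(onsets))
  if (!is.null(nuisance)) X <- cbind(X, nuisance)
  X <- cbind(X, intercept = 1)
  list(X = X, conditionCols = seq_along(onsets))
}

#' Per-vertex GLM t-statistics
#'
#' Ordinary-least-squares fit of the same design to every vertex's BOLD
#' series, returning the contrast t statistic
#' t = c'b / sqrt(s2 * c'(X'X)^-1 c) with residual variance on T - k
#' degrees of freedom. A zero-residual vertex (data exactly in the design
#' span) would give an infinite t; such values are capped at
#' \code{tMax} with a warning.
#'
#' @param bold T x s matrix of BOLD series (one column per vertex).
#' @param design design matrix (T x k, full column rank) or the list
#'   returned by [glmDesign()].
#' @param contrast length-k contrast vector.
#' @param tMax cap for degenerate (zero-residual) t values.
#' @return numeric vector of s t-statistics with attribute \code{"dof"}.
#' @export
glmTmap <- function(bold, design, contrast, tMax = 1e6) {
  if (is.list(design) && !is.null(design$X)) design <- design$X
  X <- as.matrix(design)
  stopifnot(is.matrix(bold), nrow(bold) == nrow(X))
  if (!all(is.finite(bold)) || !all(is.finite(X)))
    stop("non-finite values in bold data or design")
  k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  Tn <- nrow(X)
  if (Tn <= k) stop("need more scans than regressors (T > k)")
  stopifnot(length(contrast) == k)
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- qr.coef(qrX, bold)               # k x s
  resid <- bold - X %*% beta
  dof <- Tn - k
  sigma2 <- colSums(resid^2) / dof
  cb <- drop(crossprod(contrast, beta))
  cvc <- drop(crossprod(contrast, XtXinv %*% contrast))
  se <- sqrt(sigma2 * cvc)
  tval <- ifelse(se > 0, cb / se, sign(cb) * Inf)
  tval[se == 0 & cb == 0] <- 0
  over <- abs(tval) > tMax
  if (any(over)) {
    warning(sum(over), " degenerate (near-zero-residual) vertex/vertices: ",
            "t capped at ", tMax)
    tval[over] <- sign(tval[over]) * tMax
  }
  structure(tval, dof = dof)
}

#' Construct an unthresholded ActivationMap from a statistic vector
#'
#' @param stat per-vertex statistic values.
#' @param statType "t" or "p".
#' @param dof degrees of freedom for a t statistic (taken from the
#'   \code{"dof"} attribute of [glmTmap()] output when present).
#' @return an [ActivationMap-class].
#' @export
activationMap <- function(stat, statType = c("t", "p"), dof = NULL) {
  statType <- match.arg(statType)
  if (is.null(dof)) dof <- attr(stat, "dof") %||% NA_real_
  new("ActivationMap", stat = as.numeric(stat), statType = statType,
      dof = as.numeric(dof), clusterLabels = integer(0),
      thresholdState = "unthresholded")
}

## vertex p-values for thresholding; two-sided for t
.vertex_p <- function(map) {
  if (map@statType == "p") return(map@stat)
  if (!is.finite(map@dof))
    stop("t-statistic map needs degrees of freedom to threshold by p")
  2 * stats::pt(abs(map@stat), df = map@dof, lower.tail = FALSE)
}

#' Threshold an activation map and label clusters
#'
#' Removes vertices whose (two-sided, for t maps) p-value fails the
#' significance level, labels the survivors by connected components under
#' the mesh adjacency, and discards components smaller than the
#' cluster-extent threshold. Survival is inclusive: a cluster of exactly
#' \code{minCluster} vertices is kept.
#'
#' @param map an [ActivationMap-class] (thresholded or not; re-thresholding
#'   starts from the raw statistics).
#' @param src the [SourceSpace-class] providing the mesh adjacency.
#' @param p significance level in (0, 1); default 0.05.
#' @param minCluster minimum surviving cluster extent; default 4 vertices.
#' @return the map with \code{clusterLabels} set (0 = inactive) and
#'   threshold state "thresholded". Cluster labels are 1..K in decreasing
#'   cluster size order (ties by smallest vertex index).
#' @export
thresholdMap <- function(map, src, p = 0.05, minCluster = 4L) {
  stopifnot(is(map, "ActivationMap"), is(src, "SourceSpace"))
  stopifnot(p > 0, p < 1, minCluster >= 1L)
  s <- length(map@stat)
  if (s != nSources(src))
    stop(sprintf("map has %d vertices but source space has %d", s,
                 nSources(src)))
  pv <- .vertex_p(map)
  surviving <- which(pv < p)
  labels <- integer(s)
  if (length(surviving)) {
    comp <- .mesh_components(surviving, adjacency(src))
    sizes <- tabulate(comp)
    keep <- which(sizes >= minCluster)
    ## relabel 1..K by decreasing size, ties by first vertex
    ord <- keep[order(-sizes[keep], vapply(keep, function(k)
      min(surviving[comp == k]), 1L))]
    for (newlab in seq_along(ord))
      labels[surviving[comp == ord[newlab]]] <- newlab
  }
  initialize(map, thresholdP = p, minCluster = as.numeric(minCluster),
             clusterLabels = labels, thresholdState = "thresholded")
}

## connected components of the vertex subset under mesh adjacency (igraph)
.mesh_components <- function(subset, adj) {
  pos <- integer(max(subset))
  pos[subset] <- seq_along(subset)
  edges <- integer(0)
  for (i in subset) {
    nb <- adj[[i]]
    nb <- nb[nb > i & nb %in% subset]
    if (length(nb)) edges <- c(edges, rbind(pos[i], pos[nb]))
  }
  g <- igraph::make_graph(edges, n = length(subset), directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Partition a thresholded map into submaps
#'
#' Mode "clusters" yields one submap per connected suprathreshold cluster;
#' mode "labels" additionally splits every cluster by the source space's
#' region labels. The result is a partition of the surviving vertex set.
#'
#' @param map a thresholded [ActivationMap-class].
#' @param src the [SourceSpace-class] (supplies region labels for mode
#'   "labels").
#' @param mode "clusters" (default) or "labels".
#' @param encoding covariance-component encoding for the resulting
#'   [PriorSet-class]; see [buildComponents()].
#' @return a [PriorSet-class] (empty when no clusters survive; downstream
#'   estimation then falls back to the no-prior model).
#' @export
partitionSubmaps <- function(map, src, mode = c("clusters", "labels"),
                             encoding = c("indicator-rank1", "diagonal")) {
  mode <- match.arg(mode)
  encoding <- match.arg(encoding)
  stopifnot(is(map, "ActivationMap"))
  if (map@thresholdState != "thresholded")
    stop("map must be thresholded first (thresholdMap)")
  labs <- map@clusterLabels
  ks <- setdiff(sort(unique(labs)), 0L)
  submaps <- lapply(ks, function(k) which(labs == k))
  if (mode == "labels") {
    rl <- regionLabels(src)
    if (!length(rl))
      stop("mode 'labels' requires region labels on the source space")
    submaps <- unlist(lapply(submaps, function(sm)
      unname(split(sm, rl[sm]))), recursive = FALSE)
  }
  buildComponents(submaps, nSources(src), encoding = encoding)
}

#' Build covariance components from submaps
#'
#' Packages disjoint submaps as a [PriorSet-class] under one of two
#' encodings. "indicator-rank1" (default) takes q_i as the 0/1 indicator
#' vector of the submap and Q_i = q_i q_i' — a rank-1 all-ones block that
#' models coherent activity across the submap. "diagonal" takes
#' Q_i = diag(q_i), modelling independent within-submap sources.
#'
#' @param submaps list of 1-based vertex index vectors, non-empty and
#'   pairwise disjoint.
#' @param s total number of sources.
#' @param encoding "indicator-rank1" or "diagonal".
#' @return a [PriorSet-class].
#' @export
buildComponents <- function(submaps, s,
                            encoding = c("indicator-rank1", "diagonal")) {
  encoding <- match.arg(encoding)
  submaps <- lapply(submaps, function(x) sort(as.integer(x)))
  if (anyDuplicated(unlist(submaps)))
    stop("submaps overlap; components must be built from disjoint submaps")
  new("PriorSet", submaps = submaps, encoding = encoding,
      sourceCount = as.integer(s))
}

#' Materialise one covariance component
#'
#' @param priors a [PriorSet-class].
#' @param i component index.
#' @return sparse s x s symmetric PSD matrix Q_i.
#' @export
componentMatrix <- function(priors, i) {
  stopifnot(is(priors, "PriorSet"), i >= 1L, i <= length(priors@submaps))
  q <- priors@submaps[[i]]
  s <- priors@sourceCount
  if (priors@encoding == "indicator-rank1") {
    Matrix::sparseMatrix(i = rep(q, each = length(q)),
                         j = rep(q, times = length(q)),
                         x = 1, dims = c(s, s), symmetric = FALSE)
  } else {
    Matrix::sparseMatrix(i = q, j = q, x = 1, dims = c(s, s))
  }
}
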