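#' @include AllClasses.R
NULL

#' Accessors for stesi objects
#'
#' Small accessor generics exposing the slots of the package's S4 classes
#' without touching \code{@} directly.
#'
#' @param object an stesi S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("normals", function(object) standardGeneric("normals"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("gainMatrix", function(object) standardGeneric("gainMatrix"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("statValues", function(object) standardGeneric("statValues"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("submaps", function(object) standardGeneric("submaps"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("muLambda", function(object) standardGeneric("muLambda"))
#' @rdname accessors
#' @export
setGeneric("freeEnergyTrace", function(object) standardGeneric("freeEnergyTrace"))
#' @rdname accessors
#' @export
setGeneric("logEvidence", function(object) standardGeneric("logEvidence"))
#' @rdname accessors
#' @export
setGeneric("componentWeights", function(object) standardGeneric("componentWeights"))
#' @rdname accessors
#' @export
setGeneric("sourceCovariance", function(object) standardGeneric("sourceCovariance"))
#' @rdname accessors
#' @export
setGeneric("currentDensity", function(object) standardGeneric("currentDensity"))
#' @rdname accessors
#' @export
setGeneric("windowBoundaries", function(object) standardGeneric("windowBoundaries"))
#' @rdname accessors
#' @export
setGeneric("perWindowFit", function(object) standardGeneric("perWindowFit"))
#' @rdname accessors
#' @export
setGeneric("imagingMethod", function(object) standardGeneric("imagingMethod"))

#' @rdname accessors
#' @export
setMethod("vertices", "SourceSpace", function(object) object@vertices)
#' @rdname accessors
#' @export
setMethod("normals", "SourceSpace", function(object) object@normals)
#' @rdname accessors
#' @export
setMethod("adjacency", "SourceSpace", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("regionLabels", "SourceSpace", function(object) object@regionLabels)
#' @rdname accessors
#' @export
setMethod("gainMatrix", "LeadField", function(object) object@gain)
#' @rdname accessors
#' @export
setMethod("channelNames", "LeadField", function(object) object@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGEpochs", function(object) object@channelNames)
#' @rdname accessors
#' @export
setMethod("epochData", "EEGEpochs", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGEpochs", function(object) object@sfreq)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SourceEstimate", function(object) object@sfreq)
#' @rdname accessors
#' @export
setMethod("statValues", "ActivationMap", function(object) object@stat)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ActivationMap", function(object) object@clusterLabels)
#' @rdname accessors
#' @export
setMethod("nClusters", "ActivationMap", function(object) {
  if (object@thresholdState != "thresholded") return(NA_integer_)
  length(setdiff(unique(object@clusterLabels), 0L))
})
#' @rdname accessors
#' @export
setMethod("submaps", "PriorSet", function(object) object@submaps)
#' @rdname accessors
#' @export
setMethod("nComponents", "PriorSet", function(object) length(object@submaps))
#' @rdname accessors
#' @export
setMethod("muLambda", "ReMLFit", function(object) object@muLambda)
#' @rdname accessors
#' @export
setMethod("freeEnergyTrace", "ReMLFit", function(object) object@FTrace)
#' @rdname accessors
#' @export
setMethod("logEvidence", "ReMLFit", function(object) object@logEvidence)
#' @rdname accessors
#' @export
setMethod("componentWeights", "ReMLFit", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("sourceCovariance", "ReMLFit", function(object) object@R)
#' @rdname accessors
#' @export
setMethod("currentDensity", "SourceEstimate", function(object) object@J)
#' @rdname accessors
#' @export
setMethod("windowBoundaries", "SourceEstimate", function(object) object@windowBoundaries)
#' @rdname accessors
#' @export
setMethod("perWindowFit", "SourceEstimate", function(object) object@perWindowFit)
#' @rdname accessors
#' @export
setMethod("imagingMethod", "SourceEstimate", function(object) object@method)

#' Number of sources, channels, samples
#'
#' @param object an stesi S4 object.
#' @name dims
NULL

#' @rdname dims
#' @export
setGeneric("nSources", function(object) standardGeneric("nSources"))
#' @rdname dims
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname dims
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname dims
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname dims
#' @export
setMethod("nSources", "SourceSpace", function(object) nrow(object@vertices))
#' @rdname dims
#' @export
setMethod("nSources", "LeadField", function(object) ncol(object@gain))
#' @rdname dims
#' @export
setMethod("nSources", "PriorSet", function(object) object@sourceCount)
#' @rdname dims
#' @export
setMethod("nSources", "SourceEstimate", function(object) nrow(object@J))
#' @rdname dims
#' @export
setMethod("nChannels", "LeadField", function(object) nrow(object@gain))
#' @rdname dims
#' @export
setMethod("nChannels", "EEGEpochs", function(object) dim(object@data)[2])
#' @rdname dims
#' @export
setMethod("nSamples", "EEGEpochs", function(object) dim(object@data)[3])
#' @rdname dims
#' @export
setMethod("nSamples", "SourceEstimate", function(object) ncol(object@J))
#' @rdname dims
#' @export
setMethod("nEpochs", "EEGEpochs", function(object) dim(object@data)[1])

setMethod("show", "SourceSpace", function(object) {
  cat(sprintf("SourceSpace: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (length(object@regionLabels)) ", labelled" else ""))
})

setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d channels x %d sources [uV/(nA m)], source space '%s'\n",
              nrow(object@gain), ncol(object@gain), object@sourceSpaceId))
})

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf("EEGEpochs: %d epoch(s) x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], object@sfreq, object@t0))
})

setMethod("show", "ActivationMap", function(object) {
  cat(sprintf("ActivationMap: %d vertices (%s statistic), %s",
              length(object@stat), object@statType, object@thresholdState))
  if (object@thresholdState == "thresholded")
    cat(sprintf(" [p < %g, extent >= %d -> %d cluster(s)]",
                object@thresholdP, as.integer(object@minCluster),
                nClusters(object)))
  cat("\n")
})

setMethod("show", "PriorSet", function(object) {
  cat(sprintf("PriorSet: %d component(s) over %d sources, encoding '%s'\n",
              length(object@submaps), object@sourceCount, object@encoding))
  sizes <- vapply(object@submaps, length, 1L)
  if (length(sizes)) cat("  submap sizes:", paste(sizes, collapse = ", "), "\n")
})

setMethod("show", "ReMLFit", function(object) {
  cat(sprintf("ReMLFit: %d hyperparameter(s), %d iteration(s), %sconverged\n",
              length(object@muLambda), object@nIter,
              if (object@converged) "" else "NOT "))
  cat(sprintf("  F = %.4f; mu_lambda = %s\n", object@logEvidence,
              paste(sprintf("%.2f", object@muLambda), collapse = ", ")))
})

setMethod("show", "SourceEstimate", function(object) {
  cat(sprintf("SourceEstimate (%s): %d sources x %d samples @ %g Hz, %d window(s)\n",
              object@method, nrow(object@J), ncol(object@J), object@sfreq,
              length(object@windowBoundaries) - 1L))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:\n")
  for (i in seq_along(object@localizationError)) {
    nm <- if (length(object@patchNames) >= i) object@patchNames[i]
          else sprintf("patch %d", i)
    cat(sprintf("  %-12s loc. error %.4f m, time-course r = %.3f\n",
                nm, object@localizationError[i], object@timecourseCorr[i]))
  }
  cat(sprintf("  energy outside true support: %.3f\n", object@energyOutsideTruth))
})

setMethod("show", "SimScene", function(object) {
  cat(sprintf("SimScene: %d patch(es), %d spurious, SNR %g dB, seed %d\n",
              length(object@patches), length(object@spuriousPatches),
              object@snrDb, object@seed))
})
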