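#' @name submat-accessors
#' @title Accessors for submat classes
#' @description Small accessor generics shared by the package's classes:
#' \code{groupId} (identifier of a group-level object), \code{nSequences}
#' and \code{alignmentLength} (dimensions of an alignment), \code{clusterOf}
#' and \code{clusterSizes} (cluster membership and sizes), \code{pairCounts}
#' and \code{totalPairs} (weighted counts), \code{pairFreqs} and
#' \code{marginalFreqs} (frequencies), \code{scores} and \code{rawScores}
#' (integer and unrounded score tables), \code{relEntropy} and
#' \code{expScore} (matrix diagnostics).
#' @param x an object of the appropriate class.
#' @param ... further arguments (unused).
NULL

#' @rdname submat-accessors
#' @export
setGeneric("groupId", function(x) standardGeneric("groupId"))
#' @rdname submat-accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname submat-accessors
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))
#' @rdname submat-accessors
#' @export
setGeneric("alignedSymbols", function(x) standardGeneric("alignedSymbols"))
#' @rdname submat-accessors
#' @export
setGeneric("clusterOf", function(x) standardGeneric("clusterOf"))
#' @rdname submat-accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))
#' @rdname submat-accessors
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))
#' @rdname submat-accessors
#' @export
setGeneric("totalPairs", function(x) standardGeneric("totalPairs"))
#' @rdname submat-accessors
#' @export
setGeneric("pairFreqs", function(x) standardGeneric("pairFreqs"))
#' @rdname submat-accessors
#' @export
setGeneric("marginalFreqs", function(x) standardGeneric("marginalFreqs"))
#' @rdname submat-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname submat-accessors
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))
#' @rdname submat-accessors
#' @export
setGeneric("relEntropy", function(x) standardGeneric("relEntropy"))
#' @rdname submat-accessors
#' @export
setGeneric("expScore", function(x) standardGeneric("expScore"))

#' @rdname submat-accessors
#' @export
setMethod("groupId", "GroupAlignment", function(x) x@groupId)
#' @rdname submat-accessors
#' @export
setMethod("groupId", "ClusterAssignment", function(x) x@groupId)
#' @rdname submat-accessors
#' @export
setMethod("groupId", "PairCounts", function(x) x@groupId)
#' @rdname submat-accessors
#' @export
setMethod("groupId", "GroupFrequencies", function(x) x@groupId)

#' @rdname submat-accessors
#' @export
setMethod("nSequences", "GroupAlignment", function(x) nrow(x@symbols))
#' @rdname submat-accessors
#' @export
setMethod("alignmentLength", "GroupAlignment", function(x) ncol(x@symbols))
#' @rdname submat-accessors
#' @export
setMethod("alignedSymbols", "GroupAlignment", function(x) x@symbols)

#' @rdname submat-accessors
#' @export
setMethod("clusterOf", "ClusterAssignment", function(x) x@membership)
#' @rdname submat-accessors
#' @export
setMethod("clusterSizes", "ClusterAssignment", function(x)
  table(factor(x@membership, levels = sort(unique(x@membership)))))

#' @rdname submat-accessors
#' @export
setMethod("pairCounts", "PairCounts", function(x) x@counts)
#' @rdname submat-accessors
#' @export
setMethod("totalPairs", "PairCounts", function(x) x@totalPairs)

#' @rdname submat-accessors
#' @export
setMethod("pairFreqs", "GroupFrequencies", function(x) x@freqs)
#' @rdname submat-accessors
#' @export
setMethod("pairFreqs", "FrequencyTable", function(x) x@probs)
#' @rdname submat-accessors
#' @export
setMethod("marginalFreqs", "FrequencyTable", function(x) x@marginals)

#' @rdname submat-accessors
#' @export
setMethod("scores", "SubstitutionMatrix", function(x) x@scoresInt)
#' @rdname submat-accessors
#' @export
setMethod("rawScores", "SubstitutionMatrix", function(x) x@scoresRaw)
#' @rdname submat-accessors
#' @export
setMethod("relEntropy", "SubstitutionMatrix", function(x) x@H)
#' @rdname submat-accessors
#' @export
setMethod("expScore", "SubstitutionMatrix", function(x) x@E)

#' @export
setMethod("show","GroupAlignment", function(object) {
  cat("GroupAlignment '", object@groupId, "': ", nrow(object@symbols),
      " sequences x ", ncol(object@symbols), " columns\n", sep = "")
})

#' @export
setMethod("show","ClusterAssignment", function(object) {
  cs <- clusterSizes(object)
  cat("ClusterAssignment '", object@groupId, "' at t = ", object@threshold,
      "%: ", length(object@membership), " sequences in ", length(cs),
      " cluster(s)\n", sep = "")
})

#' @export
setMethod("show","PairCounts", function(object) {
  cat("PairCounts '", object@groupId, "': N_k = ",
      format(object@totalPairs), " weighted pairs\n", sep = "")
})

#' @export
setMethod("show","FrequencyTable", function(object) {
  cat("FrequencyTable over ", object@nGroups, " group(s), mode '",
      object@mode, "'\n", sep = "")
})

#' @export
setMethod("show","SubstitutionMatrix", function(object) {
  cat("SubstitutionMatrix (", nrow(object@scoresInt), " x ",
      ncol(object@scoresInt), ")", sep = "")
  if (!is.na(object@threshold))
    cat(", clustering threshold t = ", object@threshold, sep = "")
  cat("\n  relative entropy H = ", format(round(object@H, 4)),
      " bits, expected score E = ", format(round(object@E, 4)),
      " bits\n", sep = "")
})
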