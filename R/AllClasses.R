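#' GroupAlignment: one seed MSA
#'
#' A single seed multiple sequence alignment ("group"): a rectangular table
#' of canonicalized residue/gap symbols, one row per sequence. All rows have
#' the same aligned length; symbols are restricted to the 20 canonical amino
#' acids, the ambiguity codes B, J, Z, X and the gap symbol \code{-}.
#'
#' @slot groupId single character, the group (family) identifier.
#' @slot symbols character matrix (sequences x columns) of canonical symbols,
#'   with sequence identifiers as rownames.
#'
#' @aliases GroupAlignment-class
#' @exportClass GroupAlignment
setClass("GroupAlignment",
  representation(groupId = "character", symbols = "matrix"))

setValidity("GroupAlignment", function(object) {
  m <- object@symbols
  if (length(object@groupId) != 1L) return("groupId must be a single string")
  if (!is.character(m)) return("symbols must be a character matrix")
  if (nrow(m) < 1L || ncol(m) < 1L)
    return("alignment must have at least one sequence and one column")
  if (is.null(rownames(m))) return("symbols must carry sequence ids as rownames")
  bad <- !(m %in% c(EXTENDED_AA, GAP_SYMBOL))
  if (any(bad))
    return(paste0("non-canonical symbol(s): ",
                  paste(unique(m[bad]), collapse = ", ")))
  TRUE
})

#' Construct a GroupAlignment
#'
#' @param groupId group identifier.
#' @param sequences named character vector of equal-length aligned strings,
#'   or a character matrix of single symbols with rownames.
#' @param nonstandard passed to [canonicalizeSymbols()].
#' @return a [GroupAlignment-class] object.
#' @examples
#' GroupAlignment("toy", c(s1 = "ACD-G", s2 = "ACE-G"))
#' @export
GroupAlignment <- function(groupId, sequences, nonstandard = "to-X") {
  if (is.matrix(sequences)) {
    m <- sequences
    m[] <- canonicalizeSymbols(as.vector(m), nonstandard)
  } else {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment in group '", groupId, "': row lengths ",
           paste(unique(lens), collapse = ", "))
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
    m <- do.call(rbind, lapply(sequences, function(s)
      canonicalizeSymbols(s, nonstandard)))
    rownames(m) <- ids
  }
  new("GroupAlignment", groupId = as.character(groupId), symbols = m)
}

#' ClusterAssignment: identity-threshold partition of a group
#'
#' Partition of a group's sequences into clusters at threshold \code{t}
#' (percent identity): two sequences share a cluster iff they are connected
#' by a chain of pairwise similarities at or above \code{t}.
#'
#' @slot groupId group identifier.
#' @slot membership integer vector, cluster id per sequence (1-based).
#' @slot threshold the clustering threshold t in percent.
#'
#' @aliases ClusterAssignment-class
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(groupId = "character", membership = "integer",
                 threshold = "numeric"))

setValidity("ClusterAssignment", function(object) {
  if (length(object@membership) < 1L) return("empty membership")
  if (anyNA(object@membership)) return("NA cluster id")
  if (object@threshold < 0 || object@threshold > 100)
    return("threshold must be in [0, 100]")
  TRUE
})

#' PairCounts: cluster-weighted pair counts for one group
#'
#' Symmetric weighted pair-count table over the extended alphabet for one
#' group, after ambiguity redistribution. The cell (x, y) holds the total
#' weight of observed unordered residue pairs \{x, y\} (mirrored across the
#' diagonal). \code{totalPairs} is the total weight of observed pairs,
#' counting each observed pair once regardless of redistribution.
#'
#' @slot groupId group identifier.
#' @slot counts 24 x 24 symmetric numeric matrix.
#' @slot totalPairs total weighted number of observed residue pairs (N_k).
#' @slot nSeq number of sequences in the group (s_k), kept for the
#'   per-sequence normalization mode.
#'
#' @aliases PairCounts-class
#' @exportClass PairCounts
setClass("PairCounts",
  representation(groupId = "character", counts = "matrix",
                 totalPairs = "numeric", nSeq = "integer"))

setValidity("PairCounts", function(object) {
  m <- object@counts
  if (!identical(dim(m), c(24L, 24L))) return("counts must be 24 x 24")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
    return("counts must be symmetric")
  if (any(m < 0)) return("negative pair count")
  if (object@totalPairs < 0) return("negative totalPairs")
  TRUE
})

#' GroupFrequencies: normalized pair frequencies for one group
#'
#' @slot groupId group identifier.
#' @slot freqs 24 x 24 symmetric numeric matrix of pair frequencies
#'   (unordered-pair semantics, mirrored).
#' @slot mode normalization mode used ("total-pairs" or "per-sequence").
#'
#' @aliases GroupFrequencies-class
#' @exportClass GroupFrequencies
setClass("GroupFrequencies",
  representation(groupId = "character", freqs = "matrix", mode = "character"))

#' FrequencyTable: database-wide pair frequencies
#'
#' Accumulated pair frequencies over all groups, rescaled so the mass on
#' distinct unordered canonical pairs is 1. Ambiguous-symbol cells are kept
#' (rescaled by the same constant) for scoring ambiguity rows.
#'
#' @slot probs 24 x 24 symmetric numeric matrix, unordered-pair semantics.
#' @slot marginals named numeric vector over the extended alphabet; the 20
#'   canonical marginals sum to 1, ambiguous marginals are the sums over
#'   their expansion sets.
#' @slot mode normalization mode propagated from the groups.
#' @slot nGroups number of groups accumulated.
#'
#' @aliases FrequencyTable-class
#' @exportClass FrequencyTable
setClass("FrequencyTable",
  representation(probs = "matrix", marginals = "numeric",
                 mode = "character", nGroups = "integer"))

setValidity("FrequencyTable", function(object) {
  p <- object@probs
  if (!identical(dim(p), c(24L, 24L))) return("probs must be 24 x 24")
  if (any(p < 0)) return("negative frequency")
  cm <- canonicalMass(p)
  if (abs(cm - 1) > 1e-9)
    return(sprintf("canonical unordered mass is %.12f, not 1", cm))
  TRUE
})

#' SubstitutionMatrix: rounded integer log-odds scores
#'
#' Final substitution matrix: symmetric integer scores in bits over the
#' extended alphabet, together with the unrounded scores and the standard
#' diagnostics (relative entropy H and expected score E, both in bits).
#'
#' @slot scoresInt symmetric integer score matrix.
#' @slot scoresRaw symmetric numeric (unrounded) score matrix.
#' @slot H relative entropy in bits of the canonical score table.
#' @slot E expected score in bits under independent residue pairing.
#' @slot threshold clustering threshold the matrix was built at (NA when
#'   built directly from a frequency table of unknown provenance).
#' @slot meta named list of construction metadata.
#'
#' @aliases SubstitutionMatrix-class
#' @exportClass SubstitutionMatrix
setClass("SubstitutionMatrix",
  representation(scoresInt = "matrix", scoresRaw = "matrix",
                 H = "numeric", E = "numeric", threshold = "numeric",
                 meta = "list"))

setValidity("SubstitutionMatrix", function(object) {
  si <- object@scoresInt; sr <- object@scoresRaw
  if (!identical(dim(si), dim(sr))) return("score tables differ in shape")
  if (!isTRUE(all.equal(si, t(si)))) return("integer scores not symmetric")
  if (any(abs(si - sr) > 0.5 + 1e-9))
    return("integer scores differ from raw scores by more than 0.5")
  TRUE
})
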