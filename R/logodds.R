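#' Marginal residue frequencies of a symmetric joint table
#'
#' Derives the single-residue marginals from a symmetric pair-frequency
#' table in unordered semantics (cell (a, b) = total frequency of the
#' unordered pair \{a, b\}, mirrored). Under the ordered-symmetric reading
#' — diagonal mass stays, off-diagonal unordered mass splits in half over
#' the two ordered cells — the marginal of \code{a} is its conservation
#' frequency plus half its substitution frequencies:
#' \deqn{p(a) = p(a,a) + \tfrac{1}{2}\sum_{b \ne a} p(a,b).}
#' If the distinct unordered entries sum to 1, so do the marginals.
#'
#' @param p symmetric numeric matrix with dimnames (any alphabet).
#' @return named numeric vector of marginals.
#' @examples
#' p <- matrix(c(.5, .2, .2, .1), 2, 2, dimnames = list(c("A","C"), c("A","C")))
#' marginalsFromJoint(p)  # A 0.6, C 0.2
#' @export
marginalsFromJoint <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  diag(p) + (rowSums(p) - diag(p)) / 2
}

## marginals over the extended alphabet: canonical from the joint,
## ambiguous as the sum over the expansion set
extendedMarginals <- function(p) {
  mc <- marginalsFromJoint(p[CANONICAL_AA, CANONICAL_AA])
  ma <- vapply(AMBIGUOUS_AA, function(x) sum(mc[AMBIGUITY_SETS[[x]]]),
               numeric(1))
  c(mc, ma)
}

## round half away from zero ("to the next integer")
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

## ordered-symmetric reading of an unordered mirrored table
orderedJoint <- function(p) {
  po <- p / 2
  diag(po) <- diag(p)
  po
}

#' Log-odds substitution matrix from a frequency table
#'
#' Computes base-2 log-odds scores
#' \deqn{S_{ab} = \log_2 p(a,b) - \log_2\big(p(a)\,p(b)\big)}
#' under the ordered-symmetric reading of the joint (off-diagonal
#' unordered mass split in half, which makes the printed formula coincide
#' with the conventional factor-2 off-diagonal denominator), then rounds
#' half-away-from-zero to integers. Rows for the ambiguity codes are
#' scored from their own accumulated frequencies against the summed
#' marginals of their expansion sets; when an ambiguous cell carries no
#' observed mass the score falls back to averaging the canonical pair
#' frequencies of the expansion sets.
#'
#' @param f a [FrequencyTable-class].
#' @param threshold clustering threshold to record in the result (metadata
#'   only).
#' @param pseudocount additive pseudocount applied to empty canonical
#'   cells before scoring; the default 0 makes empty canonical cells a
#'   hard error (matrices built from data too sparse to observe every
#'   substitution are rejected rather than patched).
#' @param halfBits if TRUE, scores are expressed in half-bits (scaled by 2
#'   before rounding) for compatibility with common matrix files; default
#'   is whole bits.
#' @return a [SubstitutionMatrix-class] with relative entropy \code{H} and
#'   expected score \code{E} (always in bits, regardless of output scale).
#' @export
scoreMatrix <- function(f, threshold = NA_real_, pseudocount = 0,
                        halfBits = FALSE) {
  stopifnot(is(f, "FrequencyTable"))
  p <- pairFreqs(f)
  pc <- p[CANONICAL_AA, CANONICAL_AA]
  if (pseudocount > 0) {
    pc[pc == 0] <- pseudocount
    pc <- pc / canonicalMass(pc)
    p[CANONICAL_AA, CANONICAL_AA] <- pc
  }
  if (any(pc == 0)) {
    zero <- which(pc == 0 & upper.tri(pc, diag = TRUE), arr.ind = TRUE)
    stop("unobserved canonical substitution(s): ",
         paste(CANONICAL_AA[zero[, 1]], CANONICAL_AA[zero[, 2]],
               sep = "-", collapse = ", "),
         "; raise the clustering threshold, supply more alignments, ",
         "or set a pseudocount")
  }
  marg <- extendedMarginals(p)
  po <- orderedJoint(p)

  raw <- matrix(NA_real_, 24L, 24L, dimnames = list(EXTENDED_AA, EXTENDED_AA))
  ## canonical block straight from the formula
  mc <- marg[CANONICAL_AA]
  raw[1:20, 1:20] <- log2(po[1:20, 1:20]) - log2(outer(mc, mc))
  ## ambiguity rows: own cells against set marginals, with averaging fallback
  for (x in EXTENDED_AA) {
    for (y in AMBIGUOUS_AA) {
      if (x %in% AMBIGUOUS_AA && match(x, EXTENDED_AA) > match(y, EXTENDED_AA))
        next
      v <- po[x, y]
      if (v > 0) {
        s <- log2(v) - log2(marg[x] * marg[y])
      } else {
        ex <- AMBIGUITY_SETS[[x]]; ey <- AMBIGUITY_SETS[[y]]
        pAvg <- sum(po[ex, ey]) / (length(ex) * length(ey))
        mAvg <- (marg[x] / length(ex)) * (marg[y] / length(ey))
        s <- if (pAvg > 0) log2(pAvg) - log2(mAvg) else -Inf
      }
      raw[x, y] <- raw[y, x] <- s
    }
  }
  H <- relativeEntropyFrom(po, mc, raw)
  E <- expectedScoreFrom(mc, raw)
  if (halfBits) raw <- raw * 2       # output scale; H and E stay in bits
  ints <- roundHalfAway(raw)
  new("SubstitutionMatrix", scoresInt = ints, scoresRaw = raw,
      H = H, E = E, threshold = as.numeric(threshold),
      meta = list(mode = f@mode, nGroups = f@nGroups,
                  pseudocount = pseudocount, halfBits = halfBits))
}

relativeEntropyFrom <- function(po, mc, raw) {
  pb <- po[1:20, 1:20]; sb <- raw[1:20, 1:20]
  sum(ifelse(pb > 0, pb * sb, 0))
}

expectedScoreFrom <- function(mc, raw) {
  sum(outer(mc, mc) * raw[1:20, 1:20])
}

#' Relative entropy of a substitution matrix
#'
#' The expected unrounded score under the observed joint pairing
#' distribution, \eqn{H = \sum_{a,b} p_{\mathrm{ord}}(a,b) S_{ab}} over
#' canonical ordered cells — identically the Kullback-Leibler divergence
#' in bits between the observed joint and independent pairing. Zero iff
#' the joint factorizes; always non-negative.
#'
#' @param f the [FrequencyTable-class] the matrix was built from.
#' @param m the corresponding [SubstitutionMatrix-class].
#' @return relative entropy in bits.
#' @export
relativeEntropy <- function(f, m) {
  po <- orderedJoint(pairFreqs(f))
  relativeEntropyFrom(po, marginalFreqs(f)[CANONICAL_AA], rawBits(m))
}

## unrounded scores in bits regardless of the matrix's output scale
rawBits <- function(m) {
  s <- rawScores(m)
  if (isTRUE(m@meta$halfBits)) s / 2 else s
}

#' Expected score of a substitution matrix
#'
#' The expected unrounded score under independent residue pairing,
#' \eqn{E = \sum_{a,b} p(a) p(b) S_{ab}}. Must be negative for a usable
#' local-alignment matrix; it is zero only for the degenerate independent
#' joint.
#'
#' @inheritParams relativeEntropy
#' @return expected score in bits.
#' @export
expectedScore <- function(f, m) {
  expectedScoreFrom(marginalFreqs(f)[CANONICAL_AA], rawBits(m))
}

#' Build a substitution matrix from seed alignments
#'
#' End-to-end pipeline: cluster each group at threshold \code{t}, count
#' cluster-weighted ambiguity-redistributed pairs, normalize per group,
#' accumulate across groups, and score.
#'
#' @param groups a [GroupAlignment-class] or list thereof.
#' @param t clustering threshold in percent.
#' @param mode normalization mode, see [groupFrequencies()].
#' @param ... passed on to [scoreMatrix()].
#' @return a [SubstitutionMatrix-class].
#' @examples
#' gs <- simulateGroups(simConfig(nGroups = 5, seqsPerGroup = 4, L = 40,
#'                                seed = 7))
#' m <- buildSubstitutionMatrix(gs, t = 60, pseudocount = 1e-6)
#' relEntropy(m)
#' @export
buildSubstitutionMatrix <- function(groups, t, mode = "total-pairs", ...) {
  f <- buildFrequencyTable(groups, t, mode)
  scoreMatrix(f, threshold = t, ...)
}

#' @rdname buildSubstitutionMatrix
#' @return \code{buildFrequencyTable}: the accumulated
#'   [FrequencyTable-class] before scoring.
#' @export
buildFrequencyTable <- function(groups, t, mode = "total-pairs") {
  if (is(groups, "GroupAlignment")) groups <- list(groups)
  gf <- lapply(groups, function(g) {
    ca <- clusterGroup(g, t)
    groupFrequencies(countGroupPairs(g, ca), mode = mode)
  })
  accumulateFrequencies(gf)
}
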