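#' Default target joint distribution for the generator
#'
#' A realistic symmetric residue-pair joint over the 20 canonical amino
#' acids, built by inverting the half-bit BLOSUM62 log-odds scores
#' (shipped with Biostrings) against standard background frequencies:
#' \eqn{J(a,b) \propto m(a) m(b) 2^{S_{ab}/2}}, symmetrized and normalized
#' to sum to 1 over all ordered cells. This gives the generator a
#' field-standard substitution structure: conserved residues on the
#' diagonal, chemically similar residues exchanging more often.
#'
#' @return 20 x 20 symmetric positive matrix summing to 1 (ordered cells).
#' @export
defaultTargetJoint <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62[CANONICAL_AA, CANONICAL_AA]
  ## Robinson & Robinson background frequencies, the usual search-tool prior
  bg <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
          Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
          L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
          S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  bg <- bg[CANONICAL_AA] / sum(bg)
  J <- outer(bg, bg) * 2^(S / 2)
  J <- (J + t(J)) / 2
  J / sum(J)
}

#' Configuration for the seed-alignment generator
#'
#' Bundles and validates the generator parameters. The defaults describe
#' the validation conditions used throughout the package: 200 groups of 8
#' sequences by 50 columns, a 10% gap rate with geometric run lengths of
#' mean 3, a 1% ambiguity-masking rate, and no duplicates.
#'
#' @param nGroups number of groups (seed MSAs) to generate.
#' @param seqsPerGroup sequences per group: a single count or a
#'   \code{c(min, max)} range sampled uniformly per group.
#' @param L number of alignment columns.
#' @param targetJoint symmetric strictly positive 20 x 20 joint over the
#'   canonical alphabet, summing to 1 over ordered cells; the ground-truth
#'   substitution structure. Default [defaultTargetJoint()].
#' @param gapRate expected fraction of gapped positions per sequence.
#' @param gapRunMean mean length of a gap run (geometric).
#' @param ambigRate per-residue probability of masking to its ambiguity
#'   code (N/D to B, E/Q to Z, I/L to J, anything else to X).
#' @param duplicateRate per-sequence probability of appending an exact
#'   duplicate.
#' @param seed integer seed; generation is deterministic per
#'   (seed, group index).
#' @return validated configuration list of class \code{SimConfig}.
#' @export
simConfig <- function(nGroups = 200, seqsPerGroup = 8, L = 50,
                      targetJoint = defaultTargetJoint(),
                      gapRate = 0.1, gapRunMean = 3, ambigRate = 0.01,
                      duplicateRate = 0, seed = 1) {
  stopifnot(nGroups >= 1, L >= 1, all(seqsPerGroup >= 2),
            length(seqsPerGroup) %in% 1:2,
            gapRate >= 0, gapRate < 1, gapRunMean >= 1,
            ambigRate >= 0, ambigRate <= 1,
            duplicateRate >= 0, duplicateRate <= 1)
  stopifnot(is.matrix(targetJoint),
            identical(dim(targetJoint), c(20L, 20L)),
            all(targetJoint > 0),
            isTRUE(all.equal(targetJoint, t(targetJoint))),
            isTRUE(all.equal(sum(targetJoint), 1)))
  dimnames(targetJoint) <- list(CANONICAL_AA, CANONICAL_AA)
  structure(list(nGroups = nGroups, seqsPerGroup = seqsPerGroup, L = L,
                 targetJoint = targetJoint, gapRate = gapRate,
                 gapRunMean = gapRunMean, ambigRate = ambigRate,
                 duplicateRate = duplicateRate, seed = as.integer(seed)),
            class = "SimConfig")
}

## Half-kernel of the reversible pair model: the emission kernel C with
## C' diag(m) C = J, i.e. the matrix square root of the Markov kernel
## K = diag(1/m) J. Emitting two sequences independently through C from a
## common ancestor drawn from m makes their joint exactly J — the target
## joint holds for sequence PAIRS, which is what the pipeline estimates.
## (Emitting through K itself would square the kernel between leaves and
## bias the recovered log-odds.)
halfEmissionKernel <- function(J) {
  m <- rowSums(J)
  S <- J / sqrt(outer(m, m))          # symmetric, similar to K
  es <- eigen(S, symmetric = TRUE)
  ev <- pmax(es$values, 0)            # clip tiny negative eigenvalues
  sqrtS <- es$vectors %*% (sqrt(ev) * t(es$vectors))
  C <- sqrtS * sqrt(outer(1 / m, m))  # M^(-1/2) sqrtS M^(1/2)
  C[C < 0] <- 0                       # numerical noise only
  C / rowSums(C)
}

maskToAmbiguity <- function(res) {
  ifelse(res %in% c("N", "D"), "B",
  ifelse(res %in% c("E", "Q"), "Z",
  ifelse(res %in% c("I", "L"), "J", "X")))
}

#' Simulate one seed-alignment group
#'
#' Column-independent generative model: each column draws an ancestor
#' residue from the target joint's marginal, then emits every sequence's
#' residue independently from the conditional of the joint given that
#' ancestor. Gap runs of geometric length are then injected per sequence,
#' residues are masked to ambiguity codes at \code{ambigRate}, and exact
#' duplicates appended at \code{duplicateRate}. Deterministic per
#' (seed, groupIndex).
#'
#' @param cfg a [simConfig()] object.
#' @param groupIndex 1-based group index.
#' @return a [GroupAlignment-class].
#' @export
simulateGroup <- function(cfg, groupIndex) {
  stopifnot(inherits(cfg, "SimConfig"), groupIndex >= 1)
  set.seed((cfg$seed + 7919L * as.integer(groupIndex)) %% 2147483646L + 1L)
  J <- cfg$targetJoint
  marg <- rowSums(J)
  cond <- halfEmissionKernel(J)       # cond[a, ] = P(emit . | ancestor a)
  s <- if (length(cfg$seqsPerGroup) == 2L)
    sample(cfg$seqsPerGroup[1]:cfg$seqsPerGroup[2], 1L)
  else cfg$seqsPerGroup
  L <- cfg$L
  anc <- sample.int(20L, L, replace = TRUE, prob = marg)
  m <- matrix("", nrow = s, ncol = L)
  for (l in seq_len(L))
    m[, l] <- CANONICAL_AA[sample.int(20L, s, replace = TRUE,
                                      prob = cond[anc[l], ])]
  ## geometric gap runs; run starts chosen so the expected gapped fraction
  ## is gapRate
  if (cfg$gapRate > 0) {
    startP <- cfg$gapRate / cfg$gapRunMean
    for (i in seq_len(s)) {
      gapped <- logical(L)
      starts <- which(runif(L) < startP)
      for (st in starts) {
        len <- 1L + rgeom(1L, prob = 1 / cfg$gapRunMean)
        gapped[st:min(L, st + len - 1L)] <- TRUE
      }
      if (!all(gapped)) m[i, gapped] <- GAP_SYMBOL
    }
  }
  if (cfg$ambigRate > 0) {
    res <- m != GAP_SYMBOL
    mask <- res & matrix(runif(s * L) < cfg$ambigRate, s, L)
    m[mask] <- maskToAmbiguity(m[mask])
  }
  rownames(m) <- sprintf("g%d_s%d", groupIndex, seq_len(s))
  if (cfg$duplicateRate > 0) {
    dup <- which(runif(s) < cfg$duplicateRate)
    if (length(dup)) {
      dm <- m[dup, , drop = FALSE]
      rownames(dm) <- paste0(rownames(m)[dup], "_dup")
      m <- rbind(m, dm)
    }
  }
  new("GroupAlignment", groupId = sprintf("sim%04d", groupIndex),
      symbols = m)
}

#' @rdname simulateGroup
#' @return \code{simulateGroups}: a named list of [GroupAlignment-class],
#'   one per group.
#' @export
simulateGroups <- function(cfg) {
  gs <- lapply(seq_len(cfg$nGroups), function(i) simulateGroup(cfg, i))
  setNames(gs, vapply(gs, groupId, character(1)))
}

#' Ground-truth log-odds of a generator configuration
#'
#' The recovery target for the full pipeline: base-2 log-odds of the
#' configured target joint (ordered cells) against the product of its
#' marginals, \eqn{\log_2 J(a,b) - \log_2(m(a) m(b))}.
#'
#' @param cfg a [simConfig()] object.
#' @return 20 x 20 symmetric numeric matrix of log-odds in bits.
#' @export
groundTruthLogOdds <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  J <- cfg$targetJoint
  marg <- rowSums(J)
  log2(J) - log2(outer(marg, marg))
}
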