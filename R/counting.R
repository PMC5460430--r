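## Pair tables use "unordered" semantics throughout: the cell (x, y) holds
## the total weight of observed unordered residue pairs {x, y}, mirrored
## across the diagonal for convenience. Totals over *distinct* pairs
## therefore sum the upper triangle including the diagonal.

emptyPairTable <- function() {
  matrix(0, 24L, 24L, dimnames = list(EXTENDED_AA, EXTENDED_AA))
}

## mass on distinct unordered canonical pairs (upper triangle incl. diagonal)
canonicalMass <- function(p) {
  pc <- p[CANONICAL_AA, CANONICAL_AA]
  sum(pc[upper.tri(pc, diag = TRUE)])
}

## add weight v to the unordered cell {a, b} of a mirrored table
addUnordered <- function(mat, a, b, v) {
  mat[a, b] <- mat[a, b] + v
  if (a != b) mat[b, a] <- mat[b, a] + v
  mat
}

#' Cluster-weighted pair counts for one group
#'
#' Accumulates the weighted residue pair counts of one group: for every
#' alignment column and every pair of sequences with non-gap symbols at
#' that column, the pair contributes its cluster weight (0 within a
#' cluster, else 1 over the product of cluster sizes). Gap/residue and
#' gap/gap pairings are never counted. Pairs involving ambiguity codes are
#' counted directly under their own symbols and additionally redistributed
#' equally over their canonical expansions (B = \{N,D\}, Z = \{E,Q\},
#' J = \{I,L\}, X = all 20), so the canonical table carries their full
#' weight while the ambiguous cells remain observable. The total
#' \code{totalPairs} counts each observed pair's weight exactly once,
#' regardless of redistribution.
#'
#' @param g a [GroupAlignment-class].
#' @param ca the [ClusterAssignment-class] computed from \code{g}.
#' @return a [PairCounts-class].
#' @examples
#' g <- GroupAlignment("toy", c(s1 = "A", s2 = "B"))
#' pc <- countGroupPairs(g, clusterGroup(g, 100))
#' pairCounts(pc)["A", "N"]  # 0.5
#' @export
countGroupPairs <- function(g, ca) {
  stopifnot(is(g, "GroupAlignment"), is(ca, "ClusterAssignment"))
  m <- alignedSymbols(g)
  mem <- clusterOf(ca)
  if (length(mem) != nrow(m))
    stop("cluster assignment does not match group '", groupId(g), "'")
  sz <- tabulate(mem)
  w <- 1 / sz[mem]                     # per-sequence cluster weight
  s <- nrow(m); L <- ncol(m)
  memF <- factor(mem, levels = seq_along(sz))
  symF <- factor(m, levels = c(EXTENDED_AA, GAP_SYMBOL))
  dim(symF) <- NULL

  ## Ordered cross-cluster pair weights per column, accumulated over
  ## columns: M[x, y] = sum over ordered sequence pairs (i, j), i != j in
  ## different clusters, of w_i * w_j for symbols (x, y). Computed as
  ## outer(U, U) - within-cluster part, where U[x] = sum of w_i over
  ## sequences showing x.
  M <- matrix(0, 24L, 24L)
  for (l in seq_len(L)) {
    colSym <- factor(m[, l], levels = EXTENDED_AA)
    keep <- !is.na(colSym)
    if (sum(keep) < 2L) next
    ## T[x, c]: total weight of symbol x within cluster c at this column
    Tw <- matrix(0, 24L, length(sz))
    idx <- cbind(as.integer(colSym[keep]), mem[keep])
    for (r in seq_len(nrow(idx)))
      Tw[idx[r, 1L], idx[r, 2L]] <- Tw[idx[r, 1L], idx[r, 2L]] + w[keep][r]
    U <- rowSums(Tw)
    M <- M + outer(U, U) - Tw %*% t(Tw)
  }
  ## convert ordered weights to the mirrored unordered table
  n <- M
  diag(n) <- diag(M) / 2
  dimnames(n) <- list(EXTENDED_AA, EXTENDED_AA)
  Nk <- sum(M) / 2

  ## redistribute ambiguous-involving cells over canonical expansions
  n <- redistributeAmbiguity(n)
  new("PairCounts", groupId = groupId(g), counts = n,
      totalPairs = Nk, nSeq = s)
}

## equal redistribution of ambiguous pair weight over canonical expansions;
## the ambiguous cells themselves are retained (counted directly)
redistributeAmbiguity <- function(n) {
  add <- emptyPairTable()
  for (xi in 1:24) {
    for (yi in xi:24) {
      if (yi <= 20L) next                       # canonical-canonical cell
      v <- n[xi, yi]
      if (v == 0) next
      ex <- AMBIGUITY_SETS[[EXTENDED_AA[xi]]]
      ey <- AMBIGUITY_SETS[[EXTENDED_AA[yi]]]
      share <- v / (length(ex) * length(ey))
      for (a in ex) for (b in ey) add <- addUnordered(add, a, b, share)
    }
  }
  n + add
}

#' Normalize a group's pair counts to frequencies
#'
#' Turns weighted pair counts into per-group pair frequencies. For each
#' symbol pair the correction term
#' \deqn{\mu(x,y) = \frac{\sum_{a \in \Theta_x}\sum_{b \in \Theta_y} n(a,b)
#'   - n(x,y)}{|\Theta_x||\Theta_y|}}
#' compensates for counting ambiguous pairs both directly and through
#' their canonical expansions; it vanishes for canonical pairs. The
#' default mode divides \eqn{\mu + n} by the total observed pair weight
#' \eqn{N_k}; the alternative \code{"per-sequence"} mode divides by the
#' number of sequences \eqn{s_k} instead (an alternative group-size
#' normalization kept for reproduction studies).
#'
#' @param pc a [PairCounts-class].
#' @param mode \code{"total-pairs"} (divide by total pair weight, default) or
#'   \code{"per-sequence"} (divide by sequence count).
#' @return a [GroupFrequencies-class], or NULL with a warning when the
#'   group has no observed pairs in \code{"total-pairs"} mode.
#' @export
groupFrequencies <- function(pc, mode = c("total-pairs", "per-sequence")) {
  mode <- match.arg(mode)
  n <- pairCounts(pc)
  if (mode == "total-pairs" && totalPairs(pc) == 0) {
    warning("group '", groupId(pc), "' has no observed pairs; skipped")
    return(NULL)
  }
  denom <- if (mode == "total-pairs") totalPairs(pc) else pc@nSeq

  mu <- emptyPairTable()
  for (x in EXTENDED_AA) {
    ex <- AMBIGUITY_SETS[[x]]
    for (y in EXTENDED_AA) {
      ey <- AMBIGUITY_SETS[[y]]
      if (length(ex) == 1L && length(ey) == 1L) next   # canonical: mu = 0
      mu[x, y] <- (sum(n[ex, ey]) - n[x, y]) / (length(ex) * length(ey))
    }
  }
  new("GroupFrequencies", groupId = groupId(pc),
      freqs = (mu + n) / denom, mode = mode)
}

#' Accumulate group frequencies into a database-wide table
#'
#' Sums the per-group frequency tables and rescales so the mass on
#' distinct unordered canonical pairs is exactly 1 (ambiguous cells are
#' rescaled by the same constant: they double-represent mass already
#' redistributed to canonical cells and are kept only for scoring
#' ambiguity rows). Marginals are derived from the ordered-symmetric
#' reading of the table, see [marginalsFromJoint()].
#'
#' @param groups list of [GroupFrequencies-class] (NULL entries from
#'   skipped groups are dropped).
#' @return a [FrequencyTable-class].
#' @export
accumulateFrequencies <- function(groups) {
  if (is(groups, "GroupFrequencies")) groups <- list(groups)
  groups <- Filter(Negate(is.null), groups)
  if (length(groups) == 0L) stop("no groups to accumulate")
  modes <- unique(vapply(groups, function(g) g@mode, character(1)))
  if (length(modes) != 1L)
    stop("mixed normalization modes: ", paste(modes, collapse = ", "))
  p <- Reduce(`+`, lapply(groups, pairFreqs))
  cm <- canonicalMass(p)
  if (cm <= 0) stop("no canonical pair mass accumulated")
  p <- p / cm
  marg <- extendedMarginals(p)
  new("FrequencyTable", probs = p, marginals = marg,
      mode = modes, nGroups = length(groups))
}
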