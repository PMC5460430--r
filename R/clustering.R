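#' Gap-aware similarity of two aligned sequences
#'
#' Counts aligned positions carrying the same non-gap symbol (phi) and
#' normalizes by the number of residues of the shorter sequence to get the
#' fractional identity Phi in [0, 1]. Pairs with a gap on either side do
#' not count; identical ambiguity codes (B vs B) do count, B vs N does not
#' (symbol identity, not set overlap).
#'
#' @param a,b canonicalized symbol vectors of equal aligned length, or
#'   strings which are canonicalized first.
#' @return list with components \code{phi} (matching position count) and
#'   \code{Phi} (fractional identity).
#' @examples
#' pairSimilarity("ACD-G", "ACE-G")  # phi 3, Phi 0.75
#' @export
pairSimilarity <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- canonicalizeSymbols(a)
  if (is.character(b) && length(b) == 1L) b <- canonicalizeSymbols(b)
  if (length(a) != length(b))
    stop("aligned lengths differ: ", length(a), " vs ", length(b))
  resA <- isResidue(a); resB <- isResidue(b)
  lambda <- min(sum(resA), sum(resB))
  if (lambda == 0L)
    stop("all-gap sequence: similarity is undefined")
  phi <- sum(a == b & resA & resB)
  list(phi = phi, Phi = phi / lambda)
}

## full Phi matrix for a group (rows = cols = sequences); diagonal 1
phiMatrix <- function(g) {
  m <- alignedSymbols(g)
  s <- nrow(m)
  res <- m != GAP_SYMBOL
  lambda <- rowSums(res)
  if (any(lambda == 0L))
    stop("all-gap sequence(s) in group '", groupId(g), "': ",
         paste(rownames(m)[lambda == 0L], collapse = ", "))
  Phi <- diag(1, s)
  if (s > 1L) {
    for (i in seq_len(s - 1L)) {
      for (j in seq(i + 1L, s)) {
        phi <- sum(m[i, ] == m[j, ] & res[i, ] & res[j, ])
        Phi[i, j] <- Phi[j, i] <- phi / min(lambda[i], lambda[j])
      }
    }
  }
  Phi
}

#' Cluster a group's sequences at an identity threshold
#'
#' Partitions the sequences of a group into the connected components of the
#' graph that joins two sequences whenever their fractional identity Phi
#' (in percent) is at least \code{t}. The transitive closure means a
#' sequence joins a cluster as soon as it is at least \code{t}% identical
#' to any one member; the result is deterministic and independent of
#' sequence order.
#'
#' @param g a [GroupAlignment-class].
#' @param t clustering threshold in percent, in [0, 100]. Comparison is
#'   inclusive: an edge exists iff \eqn{100 \Phi \ge t}.
#' @return a [ClusterAssignment-class].
#' @examples
#' g <- GroupAlignment("toy", c(a = "ACDEF", b = "ACDEG", c = "WWWWW"))
#' clusterGroup(g, 60)
#' @export
clusterGroup <- function(g, t) {
  stopifnot(is(g, "GroupAlignment"), t >= 0, t <= 100)
  Phi <- phiMatrix(g)
  adj <- (100 * Phi >= t)
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gr)$membership
  new("ClusterAssignment", groupId = groupId(g),
      membership = as.integer(comp), threshold = as.numeric(t))
}

#' Cluster weight of a sequence pair
#'
#' Weight with which an aligned residue pair between sequences \code{i} and
#' \code{j} enters the counts: 0 when the two sequences share a cluster
#' (a cluster counts as a single sequence), else the reciprocal of the
#' product of the two cluster sizes.
#'
#' @param ca a [ClusterAssignment-class].
#' @param i,j sequence indices, \code{i != j}.
#' @return numeric weight in [0, 1].
#' @export
pairWeight <- function(ca, i, j) {
  if (i == j) stop("self-pairs are never counted (i == j)")
  mem <- clusterOf(ca)
  if (mem[i] == mem[j]) return(0)
  sz <- tabulate(mem)
  1 / (sz[mem[i]] * sz[mem[j]])
}
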