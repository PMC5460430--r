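## Independent brute-force oracles. These deliberately re-derive every
## quantity with naive loops, sharing no code path with the package
## internals they check.

ALPH24 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
            "B", "J", "Z", "X")
EXPAND <- c(setNames(as.list(ALPH24[1:20]), ALPH24[1:20]),
            list(B = c("N", "D"), J = c("I", "L"), Z = c("E", "Q"),
                 X = ALPH24[1:20]))

## connected components over an explicit boolean adjacency, by BFS
oracleComponents <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

## phi/Phi by explicit position loop
oraclePhi <- function(a, b) {
  phi <- 0L; la <- 0L; lb <- 0L
  for (l in seq_along(a)) {
    if (a[l] != "-") la <- la + 1L
    if (b[l] != "-") lb <- lb + 1L
    if (a[l] != "-" && b[l] != "-" && a[l] == b[l]) phi <- phi + 1L
  }
  list(phi = phi, Phi = phi / min(la, lb))
}

## cluster a symbol matrix by thresholding the oracle Phi matrix
oracleCluster <- function(m, t) {
  s <- nrow(m)
  adj <- matrix(FALSE, s, s)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    adj[i, j] <- 100 * oraclePhi(m[i, ], m[j, ])$Phi >= t
  }
  oracleComponents(adj)
}

## weighted pair counts by a triple loop, redistributing each observed
## pair at observation time
oracleCounts <- function(m, comp) {
  n <- matrix(0, 24, 24, dimnames = list(ALPH24, ALPH24))
  sz <- as.vector(table(factor(comp, levels = seq_len(max(comp)))))
  Nk <- 0
  for (l in seq_len(ncol(m))) {
    for (i in seq_len(nrow(m) - 1L)) {
      for (j in seq(i + 1L, nrow(m))) {
        x <- m[i, l]; y <- m[j, l]
        if (x == "-" || y == "-") next
        if (comp[i] == comp[j]) next
        w <- 1 / (sz[comp[i]] * sz[comp[j]])
        Nk <- Nk + w
        put <- function(a, b, v) {
          n[a, b] <<- n[a, b] + v
          if (a != b) n[b, a] <<- n[b, a] + v
        }
        put(x, y, w)
        if (length(EXPAND[[x]]) > 1L || length(EXPAND[[y]]) > 1L) {
          share <- w / (length(EXPAND[[x]]) * length(EXPAND[[y]]))
          for (a in EXPAND[[x]]) for (b in EXPAND[[y]]) put(a, b, share)
        }
      }
    }
  }
  list(n = n, Nk = Nk)
}

## KL divergence in bits between an ordered joint and the product of the
## supplied marginals
oracleKL <- function(pOrd, marg) {
  h <- 0
  for (i in seq_len(nrow(pOrd))) for (j in seq_len(ncol(pOrd))) {
    if (pOrd[i, j] > 0)
      h <- h + pOrd[i, j] * log2(pOrd[i, j] / (marg[i] * marg[j]))
  }
  h
}

## marginals by brute-force summation over the ordered representation
oracleMarginals <- function(p) {
  k <- nrow(p)
  out <- numeric(k)
  for (i in seq_len(k)) {
    out[i] <- p[i, i]
    for (j in seq_len(k)) if (j != i) out[i] <- out[i] + p[i, j] / 2
  }
  setNames(out, rownames(p))
}

## coverage by exhaustive prefix enumeration: try every prefix length,
## keep those within the FP budget, take the longest, then loop over
## superfamilies
oracleCoverage <- function(hits, sf, epq, nQueries = NULL) {
  hits <- hits[hits$query != hits$target, , drop = FALSE]
  if (is.null(nQueries)) nQueries <- length(unique(hits$query))
  hits <- hits[order(hits$evalue), , drop = FALSE]
  budget <- epq * nQueries
  best <- 0L
  for (k in seq_len(nrow(hits))) {
    fp <- sum(sf[hits$query[1:k]] != sf[hits$target[1:k]])
    if (fp <= budget) best <- k
  }
  sizes <- table(sf)
  fams <- names(sizes)[sizes >= 2]
  qs <- numeric(0)
  for (f in fams) {
    ti <- 0L
    if (best > 0L) for (k in seq_len(best)) {
      if (sf[hits$query[k]] == f && sf[hits$target[k]] == f) ti <- ti + 1L
    }
    si <- sizes[[f]]
    qs <- c(qs, ti / (si^2 - si))
  }
  mean(qs)
}

## random toy group over the extended alphabet (with gaps), guaranteed to
## contain no all-gap row
randomGroup <- function(nSeq, L, pGap = 0.2, pAmbig = 0.1) {
  pool <- c(ALPH24[1:20], "B", "J", "Z", "X", "-")
  pr <- c(rep((1 - pGap - pAmbig) / 20, 20), rep(pAmbig / 4, 4), pGap)
  repeat {
    m <- matrix(sample(pool, nSeq * L, TRUE, prob = pr), nSeq, L)
    if (all(rowSums(m != "-") > 0)) break
  }
  rownames(m) <- paste0("s", seq_len(nSeq))
  m
}
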