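## Hit lists are plain data.frames with columns query, target, evalue;
## superfamily membership is a named character vector id -> superfamily.

checkHitList <- function(hits, superfamilies) {
  stopifnot(is.data.frame(hits),
            all(c("query", "target", "evalue") %in% names(hits)))
  ids <- unique(c(hits$query, hits$target))
  unlabeled <- setdiff(ids, names(superfamilies))
  if (length(unlabeled))
    stop("sequence id(s) without superfamily label: ",
         paste(head(unlabeled, 5), collapse = ", "),
         if (length(unlabeled) > 5) ", ...")
  if (!all(is.finite(hits$evalue)) || any(hits$evalue < 0))
    stop("E-values must be finite and non-negative")
  hits[hits$query != hits$target, , drop = FALSE]   # drop self-hits
}

#' Coverage of true homologous relations at an error budget
#'
#' Orders a homology hit list by E-value (ties kept in stable input
#' order), truncates it at the longest prefix whose number of false
#' positives — hits joining two different superfamilies — stays within
#' \code{epq} errors per query, and measures how many true same-superfamily
#' relations survive. The per-superfamily counts are combined with
#' quadratic normalization to damp the influence of large superfamilies:
#' \deqn{Q = \frac{1}{S} \sum_{i=1}^{S} \frac{t_i}{s_i^2 - s_i}}
#' where \eqn{t_i} is the number of retained true-positive relations with
#' query in superfamily \eqn{i} and \eqn{s_i} its sequence count.
#' Superfamilies with fewer than two sequences contribute no orderable
#' relations and are excluded from the average.
#'
#' @param hits data.frame with columns \code{query}, \code{target},
#'   \code{evalue}; self-hits are dropped.
#' @param superfamilies named character vector mapping every sequence id
#'   to its superfamily.
#' @param epq error budget: admitted false-positive relations per query
#'   (0.01 admits one false positive per 100 queries).
#' @param nQueries number of queries underlying the search; defaults to
#'   the number of distinct query ids in \code{hits}.
#' @return list with \code{Q}, per-superfamily vectors \code{t} and
#'   \code{s}, the truncation length \code{cutoffIndex}, and the number of
#'   evaluated superfamilies \code{S}.
#' @export
coverageAtEPQ <- function(hits, superfamilies, epq = 0.01,
                          nQueries = NULL) {
  stopifnot(epq > 0)
  hits <- checkHitList(hits, superfamilies)
  if (is.null(nQueries)) nQueries <- length(unique(hits$query))
  ord <- order(hits$evalue)              # stable for ties
  hits <- hits[ord, , drop = FALSE]
  sfQ <- superfamilies[hits$query]
  sfT <- superfamilies[hits$target]
  isTP <- sfQ == sfT
  fpBudget <- epq * nQueries
  fpCum <- cumsum(!isTP)
  keep <- which(fpCum <= fpBudget)
  cutoff <- if (length(keep)) max(keep) else 0L

  sTab <- table(superfamilies)
  eligible <- names(sTab)[sTab >= 2L]
  if (length(eligible) == 0L)
    stop("no superfamily with at least two sequences")
  tTab <- setNames(numeric(length(eligible)), eligible)
  if (cutoff > 0L) {
    tp <- sfQ[seq_len(cutoff)][isTP[seq_len(cutoff)]]
    cnt <- table(tp)
    tTab[names(cnt)[names(cnt) %in% eligible]] <-
      cnt[names(cnt) %in% eligible]
  }
  s <- as.numeric(sTab[eligible])
  Q <- mean(tTab / (s^2 - s))
  list(Q = Q, t = tTab, s = setNames(s, eligible),
       cutoffIndex = cutoff, S = length(eligible))
}

#' Concerted Bayesian bootstrap of coverage
#'
#' Estimates the sampling distribution of the coverage Q under variation
#' of the database composition: each replicate draws one weight per
#' sequence from a flat Dirichlet prior (scaled to mean 1), weights every
#' retained true-positive relation by the product of its query and target
#' weights, and normalizes each superfamily by the correspondingly
#' weighted quadratic term \eqn{(\sum_j w_j)^2 - \sum_j w_j^2}. The
#' retained relation set is fixed by the unweighted E-value truncation.
#'
#' @inheritParams coverageAtEPQ
#' @param reps number of bootstrap replicates (at least 2).
#' @param seed integer seed; replicates are reproducible for a fixed seed.
#' @param equalWeights if TRUE, skip the Dirichlet draw and use unit
#'   weights in every replicate (degenerate limit, for testing: the mean
#'   then equals the unweighted Q and the variance is 0).
#' @return list with \code{mean}, \code{variance}, \code{reps}, and the
#'   unweighted \code{Q}.
#' @export
bootstrapCoverage <- function(hits, superfamilies, epq = 0.01, reps = 500,
                              seed = 1, nQueries = NULL,
                              equalWeights = FALSE) {
  stopifnot(reps >= 2)
  base <- coverageAtEPQ(hits, superfamilies, epq, nQueries)
  hits <- checkHitList(hits, superfamilies)
  ids <- names(superfamilies)
  if (length(ids) < 2L) stop("need at least two labeled sequences")
  eligible <- names(base$s)
  bySf <- split(ids, superfamilies[ids])[eligible]

  ## retained TP relations, as (query, target) id pairs
  ord <- order(hits$evalue)
  hits <- hits[ord, , drop = FALSE]
  cut <- base$cutoffIndex
  tp <- if (cut > 0L) {
    h <- hits[seq_len(cut), , drop = FALSE]
    h[superfamilies[h$query] == superfamilies[h$target], c("query", "target")]
  } else hits[0L, c("query", "target")]
  tpSf <- superfamilies[tp$query]

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  qs <- vapply(seq_len(reps), function(r) {
    w <- if (equalWeights) setNames(rep(1, length(ids)), ids)
         else {
           g <- rgamma(length(ids), shape = 1)
           setNames(g / mean(g), ids)
         }
    tW <- vapply(eligible, function(sf) {
      if (nrow(tp) == 0L) return(0)
      sel <- tpSf == sf
      sum(w[tp$query[sel]] * w[tp$target[sel]])
    }, numeric(1))
    dW <- vapply(bySf, function(members)
      sum(w[members])^2 - sum(w[members]^2), numeric(1))
    mean(tW / dW)
  }, numeric(1))
  list(mean = mean(qs), variance = var(qs), reps = reps, Q = base$Q)
}

#' Z-score for a coverage difference
#'
#' Significance of the difference between two bootstrapped coverage
#' distributions M and P:
#' \deqn{Z_{M,P} = \frac{\bar{Q}_M - \bar{Q}_P}
#'   {\sqrt{(\sigma^2_M + \sigma^2_P)/N}}}
#' with N the number of bootstrap replicates. |Z| >= 1.96 is flagged
#' significant at the 95% level.
#'
#' @param meanM,varM mean and variance of distribution M.
#' @param meanP,varP mean and variance of distribution P.
#' @param n number of bootstrap replicates N.
#' @return list with \code{Z} and logical \code{significant}.
#' @export
zScore <- function(meanM, varM, meanP, varP, n) {
  stopifnot(n >= 1, varM >= 0, varP >= 0)
  num <- meanM - meanP
  den <- sqrt((varM + varP) / n)
  if (den == 0) {
    if (num == 0) return(list(Z = 0, significant = FALSE))
    warning("zero variance with differing means; Z is infinite")
    return(list(Z = sign(num) * Inf, significant = TRUE))
  }
  z <- num / den
  list(Z = z, significant = abs(z) >= 1.96)
}

## map each (sequence, column) of an alignment to the residue ordinal, and
## emit one key per aligned residue pair per column
alignedPairKeys <- function(g) {
  m <- alignedSymbols(g)
  ids <- rownames(m)
  res <- m != GAP_SYMBOL
  ords <- t(apply(res, 1L, cumsum))     # residue ordinal per (seq, col)
  keys <- character(0)
  for (l in seq_len(ncol(m))) {
    hit <- which(res[, l])
    if (length(hit) < 2L) next
    cmb <- utils::combn(hit, 2L)
    a <- paste0(ids[cmb[1L, ]], ":", ords[cbind(cmb[1L, ], l)])
    b <- paste0(ids[cmb[2L, ]], ":", ords[cbind(cmb[2L, ], l)])
    swap <- ids[cmb[1L, ]] > ids[cmb[2L, ]]   # order pair by id, not row
    keys <- c(keys, ifelse(swap, paste0(b, "|", a), paste0(a, "|", b)))
  }
  keys
}

#' Alignment quality relative to a reference (q-score)
#'
#' Fraction of residue pairs aligned in the reference MSA that are aligned
#' identically in the test MSA. A residue pair is a pair of residues from
#' two different sequences placed in the same column; residues are
#' identified by sequence id and residue ordinal, so the two alignments
#' must contain the same sequences with the same ungapped residues.
#'
#' @param test,ref [GroupAlignment-class] objects over the same sequences.
#' @return fraction in [0, 1].
#' @export
qScore <- function(test, ref) {
  stopifnot(is(test, "GroupAlignment"), is(ref, "GroupAlignment"))
  idsT <- sort(rownames(alignedSymbols(test)))
  idsR <- sort(rownames(alignedSymbols(ref)))
  if (!identical(idsT, idsR))
    stop("test and reference contain different sequence ids")
  degap <- function(g, id) {
    r <- alignedSymbols(g)[id, ]
    paste(r[r != GAP_SYMBOL], collapse = "")
  }
  for (id in idsR)
    if (!identical(degap(test, id), degap(ref, id)))
      stop("ungapped residues of '", id, "' differ between test and reference")
  refKeys <- alignedPairKeys(ref)
  if (length(refKeys) == 0L)
    stop("reference alignment contains no aligned residue pairs")
  testKeys <- alignedPairKeys(test)
  sum(refKeys %in% testKeys) / length(refKeys)
}

#' Read a hit list and superfamily map from TSV
#'
#' @param hitsPath TSV with columns query, target, evalue (header
#'   optional, detected).
#' @param mapPath TSV with columns id, superfamily.
#' @return list with \code{hits} (data.frame) and \code{superfamilies}
#'   (named character vector).
#' @export
readHitList <- function(hitsPath, mapPath) {
  firstLine <- readLines(hitsPath, n = 1L)
  hasHeader <- grepl("query", firstLine, ignore.case = TRUE)
  hits <- utils::read.delim(hitsPath, header = hasHeader,
                            stringsAsFactors = FALSE)
  if (!hasHeader) names(hits) <- c("query", "target", "evalue")
  m1 <- readLines(mapPath, n = 1L)
  mapHeader <- grepl("superfamily", m1, ignore.case = TRUE)
  map <- utils::read.delim(mapPath, header = mapHeader,
                           stringsAsFactors = FALSE)
  if (!mapHeader) names(map) <- c("id", "superfamily")
  list(hits = hits,
       superfamilies = setNames(as.character(map$superfamily), map$id))
}
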