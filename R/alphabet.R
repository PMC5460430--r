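#' @importFrom methods new validObject is slot show setValidity
#' @importFrom stats rgamma runif rgeom var cor setNames
#' @importFrom utils head
NULL

## Extended amino-acid alphabet in the conventional search-tool column order:
## the 20 canonical residues followed by the ambiguity codes.
CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AMBIGUOUS_AA <- c("B", "J", "Z", "X")
EXTENDED_AA  <- c(CANONICAL_AA, AMBIGUOUS_AA)
GAP_SYMBOL   <- "-"

## Ambiguity expansion sets: each symbol maps to the set of canonical
## residues it stands for; canonical residues are singleton sets.
AMBIGUITY_SETS <- c(
  setNames(as.list(CANONICAL_AA), CANONICAL_AA),
  list(B = c("N", "D"), J = c("I", "L"), Z = c("E", "Q"), X = CANONICAL_AA)
)

#' Canonicalize raw alignment characters
#'
#' Maps raw one-letter alignment characters onto the extended alphabet
#' (20 canonical residues plus B, J, Z, X) and a single gap symbol.
#' Lowercase letters are uppercased and both \code{.} and \code{-} become
#' the gap symbol, so insert-state columns of seed alignments are treated
#' like ordinary aligned columns. The rare residues U (selenocysteine) and
#' O (pyrrolysine) are mapped to X by default, carrying no substitution
#' information of their own.
#'
#' @param x character vector of single characters (one alignment row,
#'   already split), or a single string which is split first.
#' @param nonstandard policy for U/O: \code{"to-X"} (default) masks them to
#'   X; \code{"error"} rejects them.
#' @return character vector of canonicalized symbols.
#' @examples
#' canonicalizeSymbols("AC-.ga")
#' @export
canonicalizeSymbols <- function(x, nonstandard = c("to-X", "error")) {
  nonstandard <- match.arg(nonstandard)
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  x <- toupper(x)
  x[x %in% c(".", "-")] <- GAP_SYMBOL
  uo <- x %in% c("U", "O")
  if (any(uo)) {
    if (nonstandard == "error")
      stop("nonstandard residue(s) ", paste(unique(x[uo]), collapse = ", "),
           " present and policy is 'error'")
    x[uo] <- "X"
  }
  bad <- !(x %in% c(EXTENDED_AA, GAP_SYMBOL))
  if (any(bad))
    stop("unknown alignment character(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "))
  x
}

## TRUE for non-gap positions
isResidue <- function(x) x != GAP_SYMBOL

## index lookup into the extended alphabet
aaIndex <- function(x) match(x, EXTENDED_AA)
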