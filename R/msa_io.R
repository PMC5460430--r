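#' Read seed alignments from a Stockholm file
#'
#' Parses a (possibly multi-record) Stockholm 1.0 file into a list of
#' [GroupAlignment-class] objects, one per record. Sequence lines may be
#' wrapped; duplicated sequence names across wrapped blocks are
#' concatenated. Both \code{.} and \code{-} become the gap symbol and
#' lowercase residues (insert states in seed alignments) are uppercased,
#' so every aligned column is treated alike.
#'
#' @param path path to a Stockholm 1.0 file.
#' @param nonstandard policy for U/O residues, see [canonicalizeSymbols()].
#' @return named list of [GroupAlignment-class]; names are the \code{#=GF ID}
#'   (or \code{#=GF AC}) annotation when present, else \code{record<i>}.
#' @seealso [writeStockholm()], [readAlignedFasta()]
#' @export
readStockholm <- function(path, nonstandard = "to-X") {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty Stockholm file: ", path)
  ## split into records on the '//' terminator (header lines tolerated)
  recEnd <- grep("^//\\s*$", lines)
  recStart <- c(1L, head(recEnd, -1L) + 1L)
  if (length(recEnd) == 0L) { recStart <- 1L; recEnd <- length(lines) + 1L }
  groups <- list()
  for (r in seq_along(recStart)) {
    block <- lines[recStart[r]:(recEnd[r] - 1L)]
    block <- block[!grepl("^//\\s*$", block)]
    id <- NULL
    gf <- grep("^#=GF\\s+(ID|AC)\\s+", block, value = TRUE)
    if (length(gf)) id <- sub("^#=GF\\s+\\S+\\s+", "", gf[1L])
    seqLines <- block[!grepl("^#", block) & nzchar(trimws(block))]
    seqLines <- seqLines[!grepl("^# STOCKHOLM", seqLines)]
    if (length(seqLines) == 0L) next
    parts <- regmatches(seqLines, regexpr("^\\S+", seqLines))
    if (length(parts) != length(seqLines))
      stop("malformed sequence line in record ", r, " of ", path)
    bodies <- sub("^\\S+\\s+", "", seqLines)
    bodies <- gsub("\\s+", "", bodies)
    ## wrapped records: concatenate per id, preserving first-seen order
    ids <- unique(parts)
    seqs <- vapply(ids, function(i)
      paste(bodies[parts == i], collapse = ""), character(1))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      off <- ids[lens != lens[1L]][1L]
      stop("ragged alignment in record ", r,
           if (!is.null(id)) paste0(" ('", id, "')"), " of ", path,
           ": row '", off, "' has length ", nchar(seqs[[off]]),
           ", expected ", lens[1L])
    }
    if (is.null(id)) id <- paste0("record", r)
    groups[[id]] <- GroupAlignment(id, setNames(seqs, ids),
                                   nonstandard = nonstandard)
  }
  if (length(groups) == 0L) stop("no alignment records in ", path)
  groups
}

#' Write seed alignments as a multi-record Stockholm file
#'
#' @param groups a [GroupAlignment-class] or list thereof.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStockholm <- function(groups, path) {
  if (is(groups, "GroupAlignment")) groups <- list(groups)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in groups) {
    m <- alignedSymbols(g)
    writeLines("# STOCKHOLM 1.0", con)
    writeLines(paste("#=GF ID", groupId(g)), con)
    writeLines(paste(format(rownames(m)),
                     apply(m, 1L, paste, collapse = "")), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Read one aligned FASTA file as a group
#'
#' Reads an aligned (gapped) FASTA file via Biostrings and canonicalizes it
#' into a single [GroupAlignment-class]. All records must share one aligned
#' length.
#'
#' @param path path to an aligned FASTA file.
#' @param groupId identifier for the resulting group; defaults to the file
#'   base name.
#' @param nonstandard policy for U/O residues, see [canonicalizeSymbols()].
#' @return a [GroupAlignment-class].
#' @export
readAlignedFasta <- function(path, groupId = NULL, nonstandard = "to-X") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in FASTA file: ", path)
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment in ", path, ": record lengths ",
         paste(unique(lens), collapse = ", "))
  if (is.null(groupId))
    groupId <- sub("\\.[^.]*$", "", basename(path))
  ids <- sub("\\s.*$", "", names(ss))
  GroupAlignment(groupId, setNames(as.character(ss), ids),
                 nonstandard = nonstandard)
}

#' Write a substitution matrix in search-tool text format
#'
#' Writes the whitespace-separated square matrix dialect accepted by the
#' common search tools' custom-matrix options: \code{#} comment header
#' lines, one header row of symbols, then one labelled row of integer
#' scores per symbol. Construction metadata (threshold, relative entropy,
#' expected score) is emitted in the comment header.
#'
#' @param m a [SubstitutionMatrix-class].
#' @param path output file path.
#' @param alphabetOrder symbols to emit, in order; defaults to the full
#'   extended alphabet. All requested symbols must be present in \code{m}.
#' @param stopScore if non-NULL, append a \code{*} row/column filled with
#'   this floor score (its diagonal is conventionally 1).
#' @return \code{path}, invisibly.
#' @export
writeMatrixFile <- function(m, path, alphabetOrder = EXTENDED_AA,
                            stopScore = NULL) {
  si <- scores(m)
  missing <- setdiff(alphabetOrder, rownames(si))
  if (length(missing))
    stop("symbol(s) absent from matrix: ", paste(missing, collapse = ", "))
  tab <- si[alphabetOrder, alphabetOrder, drop = FALSE]
  syms <- alphabetOrder
  if (!is.null(stopScore)) {
    tab <- rbind(cbind(tab, `*` = as.integer(stopScore)),
                 `*` = c(rep(as.integer(stopScore), ncol(tab)), 1L))
    syms <- c(syms, "*")
  }
  hdr <- c(
    "# Log-odds substitution matrix (bits, rounded)",
    if (!is.na(m@threshold))
      sprintf("# clustering threshold t = %g", m@threshold),
    sprintf("# relative entropy H = %.4f bits", m@H),
    sprintf("# expected score E = %.4f bits", m@E))
  body <- paste0(" ", paste(sprintf("%3s", syms), collapse = " "))
  rows <- vapply(seq_along(syms), function(i)
    paste0(syms[i], " ", paste(sprintf("%3d", tab[i, ]), collapse = " ")),
    character(1))
  writeLines(c(hdr, body, rows), path)
  invisible(path)
}

#' Read a substitution matrix from search-tool text format
#'
#' @param path path to a square matrix file as written by
#'   [writeMatrixFile()] (or any published matrix in the same dialect).
#' @param onAsymmetric \code{"error"} (default) rejects an asymmetric
#'   table; \code{"symmetrize"} averages with a warning.
#' @return a [SubstitutionMatrix-class]; \code{H}, \code{E} are recomputed
#'   only if frequencies are unavailable, so they are set to \code{NA} and
#'   the raw score table equals the integer table.
#' @export
readMatrixFile <- function(path, onAsymmetric = c("error", "symmetrize")) {
  onAsymmetric <- match.arg(onAsymmetric)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no matrix content in ", path)
  syms <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  n <- length(syms)
  if (length(lines) - 1L < n)
    stop("expected ", n, " matrix rows in ", path, ", found ",
         length(lines) - 1L)
  tab <- matrix(NA_real_, n, n, dimnames = list(syms, syms))
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(fields) != n + 1L)
      stop("row ", i, " of ", path, " has ", length(fields) - 1L,
           " scores, expected ", n, " (missing row label?)")
    if (!fields[1L] %in% syms)
      stop("unknown row label '", fields[1L], "' in ", path)
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) stop("non-numeric entry in row ", fields[1L])
    if (any(vals != round(vals)))
      stop("non-integer score in row ", fields[1L], " of ", path)
    tab[fields[1L], ] <- vals
  }
  if (!isTRUE(all.equal(tab, t(tab)))) {
    if (onAsymmetric == "error")
      stop("asymmetric score table in ", path,
           " (use onAsymmetric = 'symmetrize' to average)")
    warning("asymmetric score table in ", path, "; symmetrizing by average")
    tab <- (tab + t(tab)) / 2
    if (any(tab != round(tab)))
      stop("symmetrization produced non-integer scores in ", path)
  }
  new("SubstitutionMatrix", scoresInt = tab, scoresRaw = tab,
      H = NA_real_, E = NA_real_, threshold = NA_real_,
      meta = list(source = path))
}
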