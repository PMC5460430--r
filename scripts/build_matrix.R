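#!/usr/bin/env Rscript
## Build a substitution matrix from seed alignments on the command line.
##   Rscript scripts/build_matrix.R --in seeds.sto --t 62 --out matrix.mat
## Input may be multi-record Stockholm (default) or aligned FASTA (--fasta).

suppressMessages({
  library(optparse)
  library(submat)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--in", dest = "input", type = "character",
              help = "seed MSA file (Stockholm, or FASTA with --fasta)"),
  make_option("--fasta", action = "store_true", default = FALSE,
              help = "treat input as a single aligned FASTA group"),
  make_option("--t", type = "double", default = 62,
              help = "clustering threshold in percent [default %default]"),
  make_option("--mode", type = "character", default = "total-pairs",
              help = "group normalization: total-pairs or per-sequence"),
  make_option("--pseudocount", type = "double", default = 0,
              help = "additive pseudocount for empty canonical cells"),
  make_option("--half-bits", dest = "halfBits", action = "store_true",
              default = FALSE, help = "emit half-bit scores"),
  make_option("--stop-score", dest = "stopScore", type = "integer",
              default = NA, help = "optional '*' row/column floor score"),
  make_option("--out", type = "character", default = "matrix.mat",
              help = "output matrix file [default %default]"))))

if (is.null(opts$input)) stop("--in is required")
groups <- if (opts$fasta) {
  list(readAlignedFasta(opts$input))
} else {
  readStockholm(opts$input)
}
message(length(groups), " group(s) read")

m <- buildSubstitutionMatrix(groups, t = opts$t, mode = opts$mode,
                             pseudocount = opts$pseudocount,
                             halfBits = opts$halfBits)
writeMatrixFile(m, opts$out,
                stopScore = if (is.na(opts$stopScore)) NULL
                            else opts$stopScore)
message("H = ", round(relEntropy(m), 4), " bits, E = ",
        round(expScore(m), 4), " bits -> ", opts$out)
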