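#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats optimize rnorm runif rbinom aov TukeyHSD qlogis plogis
#'   setNames quantile rpois sd ptukey pf
#' @importFrom utils head read.delim write.table packageVersion combn
NULL

## Amino-acid alphabet in MEME protein order; all PSPM columns use this order.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' PSPM: position-specific probability matrix for a fixed-width protein motif
#'
#' The scoring engine's core object: a `width x 20` matrix of per-position
#' amino-acid probabilities plus a background distribution. Columns follow the
#' MEME protein alphabet order `ACDEFGHIKLMNPQRSTVWY`. Rows sum to one; when
#' built with a positive pseudocount every entry is strictly positive, so
#' log-odds bit scores are finite.
#'
#' @slot motifId single identifier string.
#' @slot probs numeric matrix, `width` rows by 20 columns, each row a
#'   probability distribution over amino acids.
#' @slot background named numeric vector of 20 background probabilities.
#' @slot pseudocount nonnegative smoothing mass used at construction.
#' @slot nsites effective number (or total weight) of source sites.
#'
#' @seealso [buildPSPM()], [scoreWindow()], [scanOrf()], [readMemeMotif()]
#' @export
setClass("PSPM",
  representation(motifId = "character", probs = "matrix",
                 background = "numeric", pseudocount = "numeric",
                 nsites = "numeric"))

setValidity("PSPM", function(object) {
  msgs <- character()
  p <- object@probs
  if (ncol(p) != 20L || !identical(colnames(p), AA20))
    msgs <- c(msgs, "probs must have 20 columns named with the amino-acid alphabet")
  if (any(p < 0) || any(p > 1))
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (nrow(p) > 0 && any(abs(rowSums(p) - 1) > 1e-6))
    msgs <- c(msgs, sprintf("probability rows must sum to 1 (worst deviation %.3g)",
                            max(abs(rowSums(p) - 1))))
  bg <- object@background
  if (length(bg) != 20L || abs(sum(bg) - 1) > 1e-6 || any(bg <= 0))
    msgs <- c(msgs, "background must be 20 positive frequencies summing to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msgs <- c(msgs, "pseudocount must be a single nonnegative number")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PSPM motif width (number of positions)
#' @param x,object a `PSPM`
#' @export
motifWidth <- function(x) nrow(x@probs)

#' @describeIn PSPM the probability matrix
#' @export
motifProbs <- function(x) x@probs

#' @describeIn PSPM the background distribution
#' @export
motifBackground <- function(x) x@background

#' @describeIn PSPM identifier string
#' @export
motifId <- function(x) x@motifId

setMethod("show", "PSPM", function(object) {
  cons <- paste(AA20[max.col(object@probs)], collapse = "")
  cat("PSPM object '", object@motifId, "'\n", sep = "")
  cat("  width: ", motifWidth(object),
      "  nsites: ", format(object@nsites),
      "  pseudocount: ", format(object@pseudocount), "\n", sep = "")
  cat("  consensus: ", cons, "\n", sep = "")
})

#' GenomeAssembly: a nucleotide assembly with organism metadata
#'
#' Wraps a [Biostrings::DNAStringSet] of contigs together with the assembly
#' identifier, organism and plant-family labels used throughout the pipeline.
#' Contig names are unique and sequences are restricted to the alphabet
#' `{A,C,G,T,N}` (readers normalize other IUPAC codes to `N`).
#'
#' @slot assemblyId assembly identifier.
#' @slot organism organism name, matched against species-tree leaves.
#' @slot plantFamily plant family label used when aggregating analyses.
#' @slot sequences a `DNAStringSet` of contigs.
#'
#' @seealso [readGenomeFasta()], [extractOrfs()], [discoverGenes()]
#' @export
setClass("GenomeAssembly",
  representation(assemblyId = "character", organism = "character",
                 plantFamily = "character", sequences = "DNAStringSet"))

setValidity("GenomeAssembly", function(object) {
  msgs <- character()
  sq <- object@sequences
  if (length(sq) == 0L)
    msgs <- c(msgs, "assembly must contain at least one contig")
  nm <- names(sq)
  if (is.null(nm) || anyDuplicated(nm))
    msgs <- c(msgs, "contig ids must be present and unique")
  if (length(sq) && any(Biostrings::width(sq) == 0L))
    msgs <- c(msgs, "contig sequences must be non-empty")
  if (length(sq)) {
    af <- Biostrings::alphabetFrequency(sq, collapse = TRUE)
    bad <- sum(af[setdiff(names(af), c("A", "C", "G", "T", "N"))])
    if (bad > 0)
      msgs <- c(msgs, "sequences must be restricted to the {A,C,G,T,N} alphabet")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeAssembly
#'
#' @param sequences a named `DNAStringSet` (or named character vector) of
#'   contigs over `{A,C,G,T,N}`.
#' @param assemblyId,organism,family identifier strings; `organism` must match
#'   a species-tree leaf when hierarchical weighting is used.
#' @return a [GenomeAssembly-class] object.
#' @export
GenomeAssembly <- function(sequences, assemblyId, organism = assemblyId,
                           family = "unknown") {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  new("GenomeAssembly", assemblyId = assemblyId, organism = organism,
      plantFamily = family, sequences = sequences)
}

#' @describeIn GenomeAssembly assembly identifier
#' @param x,object a `GenomeAssembly`
#' @export
assemblyId <- function(x) x@assemblyId

#' @describeIn GenomeAssembly organism label
#' @export
organism <- function(x) x@organism

#' @describeIn GenomeAssembly plant-family label
#' @export
plantFamily <- function(x) x@plantFamily

#' @describeIn GenomeAssembly contig sequences as a `DNAStringSet`
#' @export
contigs <- function(x) x@sequences

setMethod("show", "GenomeAssembly", function(object) {
  cat("GenomeAssembly '", object@assemblyId, "' (", object@organism,
      ", ", object@plantFamily, ")\n", sep = "")
  cat("  ", length(object@sequences), " contig(s), ",
      sum(Biostrings::width(object@sequences)), " nt total\n", sep = "")
})

#' SignalScorer: pluggable secretion-signal scoring contract
#'
#' A deterministic scorer for N-terminal secretion signals. `scoreFun` maps an
#' amino-acid prefix (the putative protein from a candidate start codon) to a
#' likelihood-like value in `[0, 1]`; higher means more signal-like.
#' `cleavageFun` returns the predicted signal length (cleavage occurs after
#' that many residues). The built-in implementation is
#' [heuristicSignalScorer()]; scores from an external predictor can be wired
#' in through the same contract.
#'
#' @slot name scorer name.
#' @slot scoreFun function(prefix character) -> numeric in `[0, 1]`.
#' @slot cleavageFun function(prefix character) -> integer signal length.
#' @export
setClass("SignalScorer",
  representation(name = "character", scoreFun = "function",
                 cleavageFun = "function"))

#' Score a candidate prefix with a SignalScorer
#' @param scorer a [SignalScorer-class]
#' @param prefix amino-acid string starting at a candidate start codon
#' @return numeric score in `[0, 1]`
#' @export
signalScore <- function(scorer, prefix) scorer@scoreFun(prefix)

#' Predicted cleavage site (signal length) for a prefix
#' @inheritParams signalScore
#' @return integer: the signal peptide length (cleavage after this residue)
#' @export
cleavageSite <- function(scorer, prefix) scorer@cleavageFun(prefix)

setMethod("show", "SignalScorer", function(object) {
  cat("SignalScorer '", object@name, "'\n", sep = "")
})
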