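## Canonical peptide-gene discovery in genome assemblies: six-frame ORF
## extraction, domain scanning, start-codon / secretion-signal selection and
## prepropeptide architecture parsing. All genomic coordinates are 0-based,
## half-open, on the forward strand; strand is {+,-}.

## All six leucine codons plus ATG; non-ATG starts are accepted because
## leucine start codons are documented in plant genes.
DEFAULT_START_CODONS <- c("ATG", "TTA", "TTG", "CTT", "CTC", "CTA", "CTG")

#' Extract open reading frames from all six frames of an assembly
#'
#' An ORF is a maximal stop-free amino-acid run between in-frame stop codons
#' (runs abutting contig ends are kept without requiring a flanking stop).
#' Codons containing `N` translate to `X` and do not terminate a run. Runs
#' with at least `min_orf_len` residues are emitted.
#'
#' @param assembly a [GenomeAssembly-class].
#' @param min_orf_len minimum ORF length in amino acids (inclusive;
#'   default 50).
#' @return data.frame with one row per ORF: `orf_id`, `contig`, `strand`,
#'   `frame` (0-2), `start`/`end` (forward-strand, 0-based half-open),
#'   `aa_len`, `has_stop` (TRUE when a stop codon follows the run), `aa`
#'   (run amino acids) and `nt` (in-frame, strand-corrected nucleotides).
#' @export
extractOrfs <- function(assembly, min_orf_len = 50) {
  stopifnot(is(assembly, "GenomeAssembly"))
  sq <- contigs(assembly)
  out <- vector("list", 0L)
  for (ci in seq_along(sq)) {
    contig_id <- names(sq)[ci]
    L <- Biostrings::width(sq)[ci]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") sq[[ci]] else
        Biostrings::reverseComplement(sq[[ci]])
      for (f in 0:2) {
        n_codon <- (L - f) %/% 3L
        if (n_codon < 1L) next
        sub <- Biostrings::subseq(s, f + 1L, f + 3L * n_codon)
        aa_str <- as.character(suppressWarnings(
          Biostrings::translate(sub, if.fuzzy.codon = "X")))
        runs <- gregexpr("[^*]+", aa_str)[[1]]
        if (runs[1] == -1L) next
        lens <- attr(runs, "match.length")
        for (k in seq_along(runs)) {
          la <- lens[k]
          if (la < min_orf_len) next
          i1 <- as.integer(runs[k])          # 1-based aa index in frame
          nt_s <- f + 3L * (i1 - 1L)         # 0-based on scanned strand
          nt_e <- nt_s + 3L * la
          if (strand == "+") { fs <- nt_s; fe <- nt_e }
          else { fs <- L - nt_e; fe <- L - nt_s }
          out[[length(out) + 1L]] <- data.frame(
            orf_id = sprintf("%s:%s:%d:%d", contig_id, strand, f, fs),
            contig = contig_id, strand = strand, frame = f,
            start = fs, end = fe, aa_len = la,
            has_stop = (i1 + la - 1L) < nchar(aa_str),
            aa = substr(aa_str, i1, i1 + la - 1L),
            nt = as.character(Biostrings::subseq(sub, 3L * (i1 - 1L) + 1L,
                                                 3L * (i1 + la - 1L))),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(orf_id = character(), contig = character(),
                      strand = character(), frame = integer(),
                      start = integer(), end = integer(), aa_len = integer(),
                      has_stop = logical(), aa = character(),
                      nt = character()))
  do.call(rbind, out)
}

## Kyte-Doolittle hydropathy values
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)

## Smallness weights for the (-3, -1) cleavage rule
SMALL_RESIDUE <- c(A = 1.0, G = 0.9, S = 0.9, C = 0.8, T = 0.7, V = 0.4)

#' Built-in heuristic secretion-signal scorer
#'
#' A deterministic [SignalScorer-class] combining the three classical signal
#' peptide features: (a) positive charge (K/R count) in residues 2-5 of the
#' n-region, (b) the maximal mean Kyte-Doolittle hydropathy over 8-residue
#' windows within residues 6-20 (h-region), and (c) small residues at the -3
#' and -1 positions of the best candidate cleavage site, searched over signal
#' lengths 15-30. The three features are combined linearly and mapped through
#' a logistic to `[0, 1]`:
#' `score = plogis(1.2*min(charge, 2) + 0.9*(hyd - 1.5) + 1.4*small - 3.2)`.
#' Prefixes shorter than 15 residues score 0. The predicted cleavage site is
#' the signal length maximizing the smallness term (earliest on ties).
#'
#' @return a [SignalScorer-class].
#' @export
heuristicSignalScorer <- function() {
  featurize <- function(prefix) {
    v <- strsplit(toupper(prefix), "")[[1]]
    n <- length(v)
    if (n < 15L) return(NULL)
    charge <- sum(v[2:min(5L, n)] %in% c("K", "R"))
    hi <- min(20L, n)
    kd <- unname(KD_HYDROPATHY[v[6:hi]])
    kd[is.na(kd)] <- 0
    hyd <- if (length(kd) >= 8L)
      max(vapply(seq_len(length(kd) - 7L),
                 function(i) mean(kd[i:(i + 7L)]), numeric(1)))
    else mean(kd)
    cs <- 15:min(30L, n)
    smalls <- vapply(cs, function(c_) {
      s1 <- SMALL_RESIDUE[v[c_]]; s3 <- SMALL_RESIDUE[v[c_ - 2L]]
      sum(c(s1, s3), na.rm = TRUE)
    }, numeric(1))
    best <- which.max(smalls)
    list(charge = charge, hyd = hyd, small = smalls[best],
         cleavage = cs[best])
  }
  new("SignalScorer", name = "heuristic",
      scoreFun = function(prefix) {
        ft <- featurize(prefix)
        if (is.null(ft)) return(0)
        unname(plogis(1.2 * min(ft$charge, 2) + 0.9 * (ft$hyd - 1.5) +
                        1.4 * ft$small - 3.2))
      },
      cleavageFun = function(prefix) {
        ft <- featurize(prefix)
        if (is.null(ft)) return(NA_integer_)
        as.integer(ft$cleavage)
      })
}

#' Signal scorer backed by a precomputed score table
#'
#' Wires externally computed per-prefix signal scores (e.g. from a dedicated
#' signal peptide predictor) into the [SignalScorer-class] contract. Prefixes
#' absent from the table score 0.
#'
#' @param scores data.frame with columns `prefix`, `score` and optionally
#'   `cleavage`.
#' @return a [SignalScorer-class].
#' @export
tableSignalScorer <- function(scores) {
  stopifnot(all(c("prefix", "score") %in% names(scores)))
  lut <- setNames(scores$score, scores$prefix)
  clv <- if ("cleavage" %in% names(scores))
    setNames(as.integer(scores$cleavage), scores$prefix) else NULL
  new("SignalScorer", name = "external-table",
      scoreFun = function(prefix) {
        s <- lut[prefix]; if (is.na(s)) 0 else unname(s)
      },
      cleavageFun = function(prefix) {
        if (is.null(clv)) return(NA_integer_)
        c_ <- clv[prefix]; if (is.na(c_)) NA_integer_ else unname(c_)
      })
}

#' Select the start codon of a candidate peptide-gene ORF
#'
#' Every residue before the first domain whose underlying codon is ATG or a
#' leucine codon is a candidate start. Each candidate's downstream prefix is
#' scored with the signal scorer; the maximum-scoring candidate is chosen
#' when its score strictly exceeds `score_cutoff` (ties break to the 5'-most
#' candidate, i.e. the longest signal). Otherwise the ORF is rejected.
#'
#' @param orf_aa,orf_nt ORF amino-acid sequence and its in-frame nucleotides.
#' @param first_domain_offset 0-based offset of the first domain hit within
#'   the ORF.
#' @param scorer a [SignalScorer-class].
#' @param score_cutoff rejection threshold (strictly-greater rule;
#'   default 0.400).
#' @param start_codons codons accepted as candidate starts.
#' @return list with `start` (0-based offset), `score` and `nss_len` on
#'   success, or `rejected = TRUE` with a `reason` (`"no_start"` when no
#'   candidate codon exists, `"no_signal"` when none passes the cutoff).
#' @export
findStart <- function(orf_aa, orf_nt, first_domain_offset, scorer,
                      score_cutoff = 0.400,
                      start_codons = DEFAULT_START_CODONS) {
  if (first_domain_offset < 1L)
    return(list(rejected = TRUE, reason = "no_start"))
  pos <- seq_len(first_domain_offset) - 1L          # 0-based aa offsets
  codons <- substring(orf_nt, 3L * pos + 1L, 3L * pos + 3L)
  cand <- pos[codons %in% start_codons]
  if (!length(cand)) return(list(rejected = TRUE, reason = "no_start"))
  prefs <- substring(orf_aa, cand + 1L)
  scores <- vapply(prefs, function(p) signalScore(scorer, p), numeric(1),
                   USE.NAMES = FALSE)
  best <- which(scores == max(scores))[1]           # 5'-most on ties
  if (!(scores[best] > score_cutoff))
    return(list(rejected = TRUE, reason = "no_signal"))
  list(start = cand[best], score = scores[best],
       nss_len = cleavageSite(scorer, prefs[best]))
}

#' Parse the four-segment prepropeptide architecture
#'
#' Given an ORF, a chosen start and its non-overlapping, offset-sorted domain
#' hits, derives the canonical architecture: signal length (the scorer's
#' cleavage call), variable-region length, domain offsets and the C-terminal
#' extension. Genes whose stop codon immediately follows the final domain get
#' `cterm_len = 0` and are flagged as lacking a C-terminal extension.
#'
#' @param orf one row of [extractOrfs()] output (as a list or data.frame row).
#' @param start 0-based start offset within the ORF (from [findStart()]).
#' @param nss_len signal length reported by the scorer.
#' @param hits domain hits from [scanOrf()] on the ORF amino acids.
#' @param width domain width (default 15).
#' @return list describing the gene, or `rejected = TRUE` with a `reason`
#'   (`"domain_in_signal"` when a domain overlaps the signal region,
#'   `"no_stop"` when no stop codon bounds the C-terminus).
#' @export
parseArchitecture <- function(orf, start, nss_len, hits, width = 15L) {
  if (!isTRUE(orf$has_stop))
    return(list(rejected = TRUE, reason = "no_stop"))
  aa_len <- nchar(orf$aa)
  prepro <- substr(orf$aa, start + 1L, aa_len)
  off <- sort(hits$offset) - start                  # relative to prepropeptide
  if (any(off < 0L) || nss_len > off[1])
    return(list(rejected = TRUE, reason = "domain_in_signal"))
  var_len <- off[1] - nss_len
  cterm_len <- nchar(prepro) - (off[length(off)] + width)
  spacer_total <- if (length(off) > 1L)
    sum(diff(off) - width) else 0L
  list(prepropeptide = prepro, nss_len = as.integer(nss_len),
       var_len = as.integer(var_len), domain_offsets = as.integer(off),
       spacer_total = as.integer(spacer_total),
       cterm_len = as.integer(cterm_len), no_cterm = cterm_len == 0L)
}

#' Discovery configuration
#'
#' @param min_orf_len minimum ORF length in amino acids (inclusive).
#' @param p_cutoff motif-scan P-value cutoff.
#' @param signal_cutoff signal-score rejection threshold (strictly greater).
#' @param scorer a [SignalScorer-class].
#' @param start_codons candidate start codons.
#' @return a named list of settings for [discoverGenes()].
#' @export
discoveryConfig <- function(min_orf_len = 50, p_cutoff = 6e-11,
                            signal_cutoff = 0.400,
                            scorer = heuristicSignalScorer(),
                            start_codons = DEFAULT_START_CODONS) {
  stopifnot(min_orf_len >= 1, p_cutoff > 0, p_cutoff < 1,
            signal_cutoff >= 0, signal_cutoff < 1)
  list(min_orf_len = min_orf_len, p_cutoff = p_cutoff,
       signal_cutoff = signal_cutoff, scorer = scorer,
       start_codons = start_codons)
}

#' Discover canonical peptide genes in a genome assembly
#'
#' The end-to-end composition: [extractOrfs()] over all six frames,
#' [scanOrf()] for domain hits at the P-value cutoff, [findStart()] for
#' signal-based start selection and [parseArchitecture()] for the segment
#' model. Genes reachable from overlapping ORFs are deduplicated on their
#' CDS span; output is ordered by contig and position.
#'
#' @param assembly a [GenomeAssembly-class].
#' @param pspm the scanning [PSPM-class].
#' @param config settings from [discoveryConfig()].
#' @return data.frame of genes (one row each) with coordinates
#'   (0-based, half-open, forward strand), segment architecture, scores, CDS
#'   nucleotides and prepropeptide. Per-ORF rejections are attached as the
#'   `"rejections"` attribute.
#' @export
discoverGenes <- function(assembly, pspm, config = discoveryConfig()) {
  orfs <- extractOrfs(assembly, config$min_orf_len)
  genes <- list(); rej <- list()
  sdist <- pspmScoreDistribution(pspm)
  reject <- function(id, reason)
    rej[[length(rej) + 1L]] <<- data.frame(orf_id = id, reason = reason)
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    hits <- scanOrf(pspm, orf$aa, config$p_cutoff, score_dist = sdist)
    if (nrow(hits) == 0L) next
    fs <- findStart(orf$aa, orf$nt, min(hits$offset), config$scorer,
                    config$signal_cutoff, config$start_codons)
    if (isTRUE(fs$rejected)) { reject(orf$orf_id, fs$reason); next }
    arch <- parseArchitecture(orf, fs$start, fs$nss_len, hits,
                              motifWidth(pspm))
    if (isTRUE(arch$rejected)) { reject(orf$orf_id, arch$reason); next }
    la <- nchar(orf$aa)
    if (orf$strand == "+") {
      cds_start <- orf$start + 3L * fs$start; cds_end <- orf$end
    } else {
      cds_start <- orf$start; cds_end <- orf$end - 3L * fs$start
    }
    genes[[length(genes) + 1L]] <- data.frame(
      assembly_id = assemblyId(assembly), organism = organism(assembly),
      family = plantFamily(assembly), contig = orf$contig,
      strand = orf$strand, cds_start = cds_start, cds_end = cds_end,
      orf_id = orf$orf_id, start_offset = fs$start,
      signal_score = fs$score, nss_len = arch$nss_len,
      var_len = arch$var_len, n_domains = length(arch$domain_offsets),
      domain_offsets = paste(arch$domain_offsets, collapse = ","),
      spacer_total = arch$spacer_total, cterm_len = arch$cterm_len,
      no_cterm = arch$no_cterm,
      cds = substr(orf$nt, 3L * fs$start + 1L, 3L * la),
      prepropeptide = arch$prepropeptide, stringsAsFactors = FALSE)
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(orf_id = character(), reason = character())
  if (!length(genes)) {
    res <- data.frame()
    attr(res, "rejections") <- rejections
    return(res)
  }
  res <- do.call(rbind, genes)
  res <- res[!duplicated(res[, c("contig", "strand", "cds_start", "cds_end")]), ]
  res <- res[order(res$contig, res$cds_start, res$cds_end), ]
  res$gene_id <- sprintf("%s_G%03d", res$assembly_id, seq_len(nrow(res)))
  rownames(res) <- NULL
  res <- res[, c("gene_id", setdiff(names(res), "gene_id"))]
  attr(res, "rejections") <- rejections
  res
}

#' GC content of a nucleotide sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` is excluded from both numerator and
#' denominator. An all-`N` sequence yields `NA`.
#'
#' @param nt nucleotide string (vectorized).
#' @return numeric in `[0, 1]`, or `NA` when undefined.
#' @export
gcContent <- function(nt) {
  vapply(toupper(nt), function(s) {
    if (!nzchar(s)) stop("empty sequence")
    v <- strsplit(s, "")[[1]]
    gc <- sum(v %in% c("G", "C"))
    at <- sum(v %in% c("A", "T"))
    if (gc + at == 0L) return(NA_real_)
    gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}
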