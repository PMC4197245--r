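## Weighted PSPM construction and motif scanning with exact P-values.
##
## Weighting is two-stage: (1) a three-level equalization in which every
## domain within an ORF, every ORF within an assembly, and every assembly
## receive equal mass; (2) a lineage decay in which each domain's weight is
## multiplied by decay^depth(leaf), depth counting internal nodes from the
## root (inclusive) to the organism's leaf, down-weighting densely sampled
## lineages. Final weights are renormalized to sum to one.

#' Assign hierarchical weights to a set of motif domains
#'
#' @param domains data.frame with columns `sequence`, `orf_id`,
#'   `assembly_id` and `organism` (one row per 15-mer domain instance).
#' @param tree rooted species tree (`phylo`) whose leaves cover every
#'   organism in `domains`, or `NULL` to skip the lineage-decay stage.
#' @param decay per-internal-node decay factor in (0, 1]; the default 0.8
#'   reduces weights by 20% for each internal node on the root-to-leaf path.
#' @return `domains` with a `weight` column summing to 1.
#' @export
assignWeights <- function(domains, tree = NULL, decay = 0.8) {
  stopifnot(is.data.frame(domains),
            all(c("sequence", "orf_id", "assembly_id", "organism") %in%
                  names(domains)))
  if (nrow(domains) == 0L) stop("empty domain set")
  if (!(decay > 0 && decay <= 1)) stop("decay must lie in (0, 1]")
  orf_key <- paste(domains$assembly_id, domains$orf_id, sep = "\r")
  n_in_orf <- ave(seq_len(nrow(domains)), orf_key, FUN = length)
  ## ORFs per assembly (count distinct orf keys per assembly)
  orfs_per_asm <- tapply(orf_key, domains$assembly_id,
                         function(k) length(unique(k)))
  w <- (1 / n_in_orf) * (1 / as.numeric(orfs_per_asm[domains$assembly_id]))
  if (!is.null(tree)) {
    depths <- leafDepths(tree)
    missing_org <- setdiff(unique(domains$organism), names(depths))
    if (length(missing_org))
      stop("organism(s) absent from species tree: ",
           paste(missing_org, collapse = ", "))
    w <- w * decay^depths[domains$organism]
  }
  domains$weight <- as.numeric(w / sum(w))
  domains
}

#' Build a PSPM from weighted domain sequences
#'
#' Estimates per-position probabilities by weighted column counting with
#' Dirichlet-style smoothing:
#' `p[i, a] = (sum of weights with residue a at position i + pc * bg[a]) /
#' (total weight + pc)`. The result is independent of input row order.
#'
#' @param domains data.frame with a `sequence` column (all the same length)
#'   and optionally a `weight` column (default: equal weights).
#' @param pseudocount smoothing mass; `"auto"` (default) uses 1% of the total
#'   weight.
#' @param background named background distribution over [AA20]; default
#'   uniform 1/20.
#' @param motifId identifier for the resulting motif.
#' @return a [PSPM-class].
#' @export
buildPSPM <- function(domains, pseudocount = "auto", background = NULL,
                      motifId = "motif") {
  if (is.character(domains)) domains <- data.frame(sequence = domains)
  if (nrow(domains) == 0L) stop("empty domain set")
  seqs <- toupper(domains$sequence)
  w <- if ("weight" %in% names(domains)) domains$weight else
    rep(1, length(seqs))
  if (any(w <= 0)) stop("weights must be positive")
  wdt <- unique(nchar(seqs))
  if (length(wdt) != 1L) stop("all domain sequences must share one width")
  chars <- do.call(rbind, strsplit(seqs, ""))
  if (!all(chars %in% AA20)) stop("sequences must use the 20-AA alphabet")
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20] / sum(background)
  tot <- sum(w)
  if (identical(pseudocount, "auto")) pseudocount <- 0.01 * tot
  probs <- matrix(0, wdt, 20, dimnames = list(NULL, AA20))
  for (i in seq_len(wdt)) {
    cw <- tapply(w, factor(chars[, i], levels = AA20), sum, default = 0)
    probs[i, ] <- (cw + pseudocount * background) / (tot + pseudocount)
  }
  new("PSPM", motifId = motifId, probs = probs, background = background,
      pseudocount = pseudocount, nsites = tot)
}

## Log-odds matrix (width x 20), -Inf allowed when pseudocount was zero.
pspmLogOdds <- function(pspm) {
  log2(motifProbs(pspm) / rep(motifBackground(pspm), each = motifWidth(pspm)))
}

#' Bit score of a window against a PSPM
#'
#' `sum_i log2(p[i, window_i] / bg[window_i])`. Zero-probability cells (only
#' possible when the PSPM was built with pseudocount 0) yield `-Inf`.
#'
#' @param pspm a [PSPM-class].
#' @param window amino-acid string of length `motifWidth(pspm)`.
#' @return bit score (numeric scalar).
#' @export
scoreWindow <- function(pspm, window) {
  v <- strsplit(toupper(window), "")[[1]]
  if (length(v) != motifWidth(pspm))
    stop("window length ", length(v), " does not match motif width ",
         motifWidth(pspm))
  idx <- match(v, AA20)
  if (anyNA(idx)) return(-Inf)
  sum(pspmLogOdds(pspm)[cbind(seq_along(idx), idx)])
}

## Discretized null score distribution of a PSPM under its background model.
## Returns base (score of bin 0), bin width g, and the tail vector
## tail[k+1] = P(binned score >= k). Windows containing letters with -Inf
## log-odds never reach any finite threshold and are excluded from the
## finite-score mass.
.pspm_cache <- new.env(parent = emptyenv())

pspmScoreDistribution <- function(pspm, granularity = NULL) {
  p <- motifProbs(pspm)
  key <- paste(motifId(pspm), nrow(p),
               format(sum(p * seq_along(p)), digits = 16),
               format(sum(motifBackground(pspm) * 1:20), digits = 16),
               if (is.null(granularity)) "auto" else format(granularity),
               sep = "|")
  hit <- .pspm_cache[[key]]
  if (!is.null(hit)) return(hit)
  lod <- pspmLogOdds(pspm)
  bg <- motifBackground(pspm)
  fin <- is.finite(lod)
  if (!all(apply(fin, 1, any))) stop("motif has a position with no finite score")
  mins <- apply(ifelse(fin, lod, Inf), 1, min)
  maxs <- apply(ifelse(fin, lod, -Inf), 1, max)
  rng <- sum(maxs) - sum(mins)
  if (is.null(granularity))
    granularity <- if (rng > 0) rng / 2^17 else 1e-9
  if (!(granularity > 0)) stop("granularity must be positive")
  g <- granularity
  offmat <- matrix(NA_integer_, nrow(lod), 20, dimnames = dimnames(lod))
  dist <- 1  # P(offset sum = 0) before any position
  for (i in seq_len(nrow(lod))) {
    offs <- rep(NA_integer_, 20)
    offs[fin[i, ]] <- as.integer(round((lod[i, fin[i, ]] - mins[i]) / g))
    offmat[i, ] <- offs
    newlen <- length(dist) + max(offs[fin[i, ]])
    nd <- numeric(newlen)
    for (a in which(fin[i, ])) {
      sh <- offs[a]
      nd[(1 + sh):(length(dist) + sh)] <-
        nd[(1 + sh):(length(dist) + sh)] + dist * bg[a]
    }
    dist <- nd
  }
  tail_ <- rev(cumsum(rev(dist)))
  res <- list(base = sum(mins), g = g, tail = tail_, offsets = offmat,
              width = nrow(lod))
  .pspm_cache[[key]] <- res
  res
}

## Tail probability at an integer bin index of the discretized distribution.
## Indices below the grid return the total finite-score mass: windows
## containing zero-probability letters score -Inf and lie below any finite
## threshold, so they never enter the tail.
binTail <- function(sd, k) {
  if (k < 0L) return(sd$tail[1])
  if (k >= length(sd$tail)) return(0.0)
  sd$tail[k + 1L]
}

## Tail probability for a raw bit-score threshold. Per-position rounding can
## displace a window's binned sum by up to half a bin per position, so the
## threshold is mapped with the matching slack; at the default resolution
## (2^17 bins) the slack is far below the spacing of distinct scores.
tailLookup <- function(sd, score) {
  if (!is.finite(score)) {
    if (score == -Inf) return(1.0) else return(0.0)
  }
  k <- ceiling((score - sd$base) / sd$g - sd$width / 2 - 1e-9)
  if (k >= length(sd$tail)) return(0.0)
  if (k < 0) return(sd$tail[1])
  binTail(sd, as.integer(k))
}

#' Exact P-value of a bit-score threshold under the background model
#'
#' Computes the probability that a random window drawn from the PSPM's
#' background distribution scores at or above `threshold`, by dynamic
#' programming over discretized per-position score distributions (convolution
#' across positions). The only error source is discretization; halving the
#' granularity changes the result by well under 1% at the default resolution
#' (2^17 bins across the score range).
#'
#' @param pspm a [PSPM-class].
#' @param threshold bit-score threshold (finite).
#' @param granularity score bin width; default `score range / 2^17`.
#' @return tail probability in `[0, 1]`.
#' @export
scorePvalue <- function(pspm, threshold, granularity = NULL) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  sd <- pspmScoreDistribution(pspm, granularity)
  tailLookup(sd, threshold)
}

#' Scan an amino-acid sequence for motif hits
#'
#' Scores every window of the sequence against the PSPM, converts scores to
#' exact background P-values, keeps windows with `p <= p_cutoff`, and
#' resolves overlaps greedily by descending bit score (ties to the leftmost
#' offset). Offsets are 0-based. Sequences shorter than the motif width yield
#' an empty result.
#'
#' @param pspm a [PSPM-class].
#' @param aa amino-acid sequence to scan (may contain `X`; windows containing
#'   unknown residues never match).
#' @param p_cutoff P-value cutoff in (0, 1); the survey default is `6e-11`.
#' @param score_dist precomputed discretized score distribution from
#'   `pspmScoreDistribution()`; supplied by callers that scan many sequences
#'   against one matrix to avoid recomputing the dynamic program.
#' @return data.frame with columns `offset`, `match`, `bit_score`, `p_value`,
#'   sorted by offset.
#' @export
scanOrf <- function(pspm, aa, p_cutoff = 6e-11, score_dist = NULL) {
  if (!(p_cutoff > 0 && p_cutoff < 1)) stop("p_cutoff must lie in (0, 1)")
  wdt <- motifWidth(pspm)
  v <- strsplit(toupper(aa), "")[[1]]
  L <- length(v)
  empty <- data.frame(offset = integer(), match = character(),
                      bit_score = numeric(), p_value = numeric())
  if (L < wdt) return(empty)
  lod <- pspmLogOdds(pspm)
  idx <- match(v, AA20)
  n_win <- L - wdt + 1L
  sd <- if (is.null(score_dist)) pspmScoreDistribution(pspm) else score_dist
  scores <- numeric(n_win)
  bins <- integer(n_win)
  for (j in seq_len(wdt)) {
    contrib <- lod[j, ][idx[j:(j + n_win - 1L)]]
    contrib[is.na(contrib)] <- -Inf
    scores <- scores + contrib
    b <- sd$offsets[j, ][idx[j:(j + n_win - 1L)]]
    bins <- bins + b   # NA marks windows with unscorable letters
  }
  cand <- which(is.finite(scores) & !is.na(bins))
  if (!length(cand)) return(empty)
  ## P-values come from the same integer grid the dynamic program was run
  ## on, so a window's tail probability is exact for the discretized model
  pv <- vapply(bins[cand], function(k) binTail(sd, k), numeric(1))
  keep <- pv <= p_cutoff
  cand <- cand[keep]; pv <- pv[keep]
  if (!length(cand)) return(empty)
  ## greedy non-overlap: descending score, ties leftmost
  ord <- order(-scores[cand], cand)
  taken <- logical(0); sel <- integer(0)
  occupied <- rep(FALSE, L)
  for (k in ord) {
    span <- cand[k]:(cand[k] + wdt - 1L)
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      sel <- c(sel, k)
    }
  }
  sel <- sel[order(cand[sel])]
  data.frame(offset = cand[sel] - 1L,
             match = vapply(cand[sel], function(o)
               paste(v[o:(o + wdt - 1L)], collapse = ""), character(1)),
             bit_score = scores[cand[sel]],
             p_value = pv[sel])
}

#' Minimum bit score achieving a P-value cutoff
#'
#' Convenience inverse of [scorePvalue()]: the smallest binned score whose
#' background tail probability is at or below `p_cutoff`.
#'
#' @inheritParams scanOrf
#' @return bit-score threshold (numeric scalar).
#' @export
scoreThreshold <- function(pspm, p_cutoff = 6e-11) {
  sd <- pspmScoreDistribution(pspm)
  k <- which(sd$tail <= p_cutoff)
  if (!length(k)) return(Inf)
  sd$base + (k[1] - 1L) * sd$g
}

#' Weighted per-position frequencies and information content
#'
#' Summary statistics behind family sequence logos: the weighted column
#' distributions of a domain set and the per-position information content
#' `log2(20) - H` in bits.
#'
#' @param domains data.frame with `sequence` and optionally `weight` columns.
#' @return list with `freqs` (width x 20 matrix) and `ic` (numeric vector).
#' @export
familyLogoStats <- function(domains) {
  pspm <- buildPSPM(domains, pseudocount = 0)
  p <- motifProbs(pspm)
  h <- apply(p, 1, function(row) {
    nz <- row[row > 0]
    -sum(nz * log2(nz))
  })
  list(freqs = p, ic = log2(20) - h)
}

#' Maximum G+C count over the codons encoding an amino acid
#'
#' For each standard codon encoding `aa`, counts its G and C nucleotides and
#' returns the maximum (0..3). Used to color residues by the GC ceiling of
#' their codon families.
#'
#' @param aa single-letter amino-acid code (vectorized).
#' @return integer vector of maximum G+C counts.
#' @export
aaMaxGC <- function(aa) {
  aa <- toupper(aa)
  code <- Biostrings::GENETIC_CODE
  gc_count <- vapply(strsplit(names(code), ""), function(x)
    sum(x %in% c("G", "C")), integer(1))
  vapply(aa, function(a) {
    if (!a %in% code) stop("unknown amino acid letter: ", a)
    max(gc_count[code == a])
  }, integer(1), USE.NAMES = FALSE)
}
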