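## Pairwise ML distances, IOPD aggregation, rank/logit Tukey comparisons,
## alignment-column trimming and sitewise dN/dS profiling.

#' Global alignment of two amino-acid sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (Gotoh's three-state
#' recursion), using the integer half-bit log-odds matrix derived from the
#' JTT model ([jttLogOddsMatrix()]). A gap of length L costs
#' `gapOpening + gapExtension * L`. Defaults: gap opening 11, gap
#' extension 1. Ties in the traceback break deterministically in the fixed
#' preference order match > gap-in-second > gap-in-first (the "high road").
#'
#' @param a,b amino-acid strings.
#' @param gapOpening,gapExtension affine gap penalties (positive costs).
#' @param matrix substitution matrix; default the JTT-derived log-odds.
#' @return list with aligned strings `a` and `b` (equal length, `-` gaps)
#'   and the alignment `score`.
#' @export
alignPair <- function(a, b, gapOpening = 11, gapExtension = 1,
                      matrix = jttLogOddsMatrix()) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(va) > 0, length(vb) > 0,
            all(va %in% rownames(matrix)), all(vb %in% rownames(matrix)))
  n <- length(va); m <- length(vb)
  go <- gapOpening; ge <- gapExtension
  NEG <- -1e15
  M <- X <- Y <- base::matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1L), 1] <- -(go + ge * seq_len(n))
  if (m > 0) Y[1, 2:(m + 1L)] <- -(go + ge * seq_len(m))
  Sm <- matrix[va, vb, drop = FALSE]
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    r <- i + 1L
    M[r, jj + 1L] <- pmax(M[i, jj], X[i, jj], Y[i, jj]) + Sm[i, ]
    X[r, jj + 1L] <- pmax(pmax(M[i, jj + 1L], Y[i, jj + 1L]) - go - ge,
                          X[i, jj + 1L] - ge)
    B <- pmax(M[r, jj], X[r, jj])
    Y[r, jj + 1L] <- cummax(B + ge * jj) - go - ge * (jj + 1L)
    Y[r, jj + 1L] <- pmax(Y[r, jj + 1L], Y[r, 1] - ge * jj)
  }
  tol <- 1e-9
  ra <- character(0); rb <- character(0)
  i <- n + 1L; j <- m + 1L
  fin <- c(M[i, j], X[i, j], Y[i, j])
  state <- which(fin >= max(fin) - tol)[1]          # 1=M, 2=X, 3=Y
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      ra <- c(va[i - 1L], ra); rb <- c(vb[j - 1L], rb)
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which(prev >= max(prev) - tol)[1]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ra <- c(va[i - 1L], ra); rb <- c("-", rb)
      opened <- pmax(M[i - 1L, j], Y[i - 1L, j]) - go - ge
      if (opened >= X[i, j] - tol) {
        state <- if (M[i - 1L, j] >= Y[i - 1L, j] - tol) 1L else 3L
      }
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(vb[j - 1L], rb)
      opened <- pmax(M[i, j - 1L], X[i, j - 1L]) - go - ge
      if (opened >= Y[i, j] - tol) {
        state <- if (M[i, j - 1L] >= X[i, j - 1L] - tol) 1L else 2L
      }
      j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = max(fin))
}

#' Pairwise ML distances for a set of sequences
#'
#' Aligns every pair with [alignPair()] and estimates the JTT maximum
#' likelihood distance with [mlDistance()].
#'
#' @param seqs named character vector of amino-acid sequences.
#' @return data.frame with `id_a`, `id_b`, `distance`, `sites`, `saturated`.
#' @export
pairwiseDistances <- function(seqs) {
  stopifnot(!is.null(names(seqs)), length(seqs) >= 2)
  ids <- names(seqs)
  out <- list()
  for (j in 2:length(seqs)) {
    for (i in seq_len(j - 1L)) {
      al <- alignPair(seqs[[i]], seqs[[j]])
      d <- mlDistance(al$a, al$b)
      out[[length(out) + 1L]] <- data.frame(
        id_a = ids[i], id_b = ids[j], distance = d$distance,
        sites = d$sites, saturated = d$saturated, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Intra-organism pairwise distances aggregated by plant family
#'
#' IOPDs are ML distances between all pairs of genes (or of individual
#' domains) identified within one genome assembly, pooled across assemblies
#' of the same plant family. Assemblies contributing fewer than two
#' sequences add nothing; no cross-assembly pairs are formed.
#'
#' @param genes data.frame of discovered genes (from [discoverGenes()] or the
#'   supplementary-table reader) with columns `gene_id`, `assembly_id`,
#'   `family`, `prepropeptide` and, for domain level, `domain_offsets`.
#' @param level `"gene"` (whole prepropeptides) or `"domain"` (individual
#'   15-mers).
#' @param width domain width for `level = "domain"`.
#' @return data.frame with `family`, `assembly_id`, `id_a`, `id_b`,
#'   `distance`.
#' @export
computeIopds <- function(genes, level = c("gene", "domain"), width = 15L) {
  level <- match.arg(level)
  out <- list()
  for (asm in unique(genes$assembly_id)) {
    sub <- genes[genes$assembly_id == asm, ]
    if (level == "gene") {
      seqs <- setNames(sub$prepropeptide, sub$gene_id)
    } else {
      seqs <- c()
      for (i in seq_len(nrow(sub))) {
        offs <- as.integer(strsplit(sub$domain_offsets[i], ",")[[1]])
        dom <- substring(sub$prepropeptide[i], offs + 1L, offs + width)
        names(dom) <- sprintf("%s_d%d", sub$gene_id[i], seq_along(dom))
        seqs <- c(seqs, dom)
      }
    }
    if (length(seqs) < 2L) next
    d <- pairwiseDistances(seqs)
    d$family <- sub$family[1]
    d$assembly_id <- asm
    out[[length(out) + 1L]] <- d
  }
  if (!length(out))
    return(data.frame(family = character(), assembly_id = character(),
                      id_a = character(), id_b = character(),
                      distance = numeric()))
  res <- do.call(rbind, out)
  res[, c("family", "assembly_id", "id_a", "id_b", "distance")]
}

## Tukey HSD on a response vector; returns the full symmetric matrix of
## adjusted p-values (studentized-range distribution). Degenerate inputs with
## zero residual variance fall back to p = 1 for equal group means and p = 0
## otherwise.
.tukeyMatrix <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two values")
  fit <- aov(values ~ groups)
  lv <- levels(groups)
  M <- matrix(NA_real_, nlevels(groups), nlevels(groups),
              dimnames = list(lv, lv))
  diag(M) <- 1
  res_ms <- sum(fit$residuals^2) / fit$df.residual
  if (res_ms <= .Machine$double.eps * max(abs(values), 1)) {
    means <- tapply(values, groups, mean)
    for (i in seq_along(lv)) for (j in seq_along(lv))
      if (i != j) M[i, j] <- if (abs(means[i] - means[j]) < 1e-12) 1 else 0
    return(M)
  }
  tk <- TukeyHSD(fit)$groups
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (k in seq_len(nrow(tk))) {
    i <- prs[[k]][1]; j <- prs[[k]][2]
    M[i, j] <- M[j, i] <- tk[k, "p adj"]
  }
  M
}

#' Rank-transformed Tukey HSD comparison of groups
#'
#' Pools all values, rank-transforms them (average ranks on ties), and runs
#' Tukey's honestly-significant-difference test on the ranks. Ranking makes
#' the comparison robust to the multimodality, skew and unequal variances
#' typical of pooled pairwise-distance distributions.
#'
#' @param values numeric vector.
#' @param groups group labels, parallel to `values`.
#' @return symmetric matrix of multiplicity-adjusted p-values.
#' @export
rankTukey <- function(values, groups) {
  .tukeyMatrix(rank(values, ties.method = "average"), groups)
}

#' Logit-transformed Tukey HSD comparison of proportions
#'
#' Maps proportions (e.g. per-gene GC content) to log-odds and runs Tukey's
#' HSD on the transformed values. With `adjust = TRUE` (default) the standard
#' small-sample smoothing `p <- (p*(n-1) + 0.5)/n` is applied first so exact
#' 0 and 1 remain finite; without it such values are an error.
#'
#' @param values proportions in `[0, 1]`.
#' @param groups group labels.
#' @param adjust apply the smoothing adjustment.
#' @return symmetric matrix of multiplicity-adjusted p-values.
#' @export
logitTukey <- function(values, groups, adjust = TRUE) {
  if (adjust) {
    n <- length(values)
    values <- (values * (n - 1) + 0.5) / n
  }
  if (any(values <= 0 | values >= 1))
    stop("values at 0 or 1 require adjust = TRUE")
  .tukeyMatrix(qlogis(values), groups)
}

#' Trim poorly aligned columns by gap-score distribution
#'
#' A documented approximation of the gappyout strategy: per-column gap
#' fractions are computed, their sorted unique values inspected, and the cut
#' placed at the steepest drop (largest jump) of the distribution; columns
#' with gap fraction at or below the value preceding the jump are kept.
#' Gapless alignments are returned unchanged.
#'
#' @param msa character vector of aligned, equal-length sequences (gaps `-`).
#' @return list with `msa` (trimmed sequences) and `kept` (1-based indices of
#'   retained columns for coordinate mapping).
#' @export
trimColumns <- function(msa) {
  M <- do.call(rbind, strsplit(msa, ""))
  if (length(unique(nchar(msa))) != 1L) stop("alignment must be rectangular")
  gap_frac <- colMeans(M == "-")
  u <- sort(unique(gap_frac))
  thr <- if (length(u) == 1L) u[1] else u[which.max(diff(u))]
  kept <- which(gap_frac <= thr)
  if (!length(kept)) stop("empty_after_trim: no columns retained")
  trimmed <- apply(M[, kept, drop = FALSE], 1, paste, collapse = "")
  list(msa = unname(trimmed), kept = kept)
}

## --- sitewise dN/dS by pathway counting ------------------------------------

.dnds_env <- new.env(parent = emptyenv())

codonTable <- function() {
  if (is.null(.dnds_env$tab)) {
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    aa <- unname(code)
    ## per-codon expected synonymous/non-synonymous site counts: each of the
    ## three positions contributes the fraction of its non-stop single-base
    ## changes that are synonymous.
    syn_sites <- vapply(codons, function(cd) {
      v <- strsplit(cd, "")[[1]]
      s <- 0
      for (p in 1:3) {
        alts <- setdiff(c("A", "C", "G", "T"), v[p])
        alt_codons <- vapply(alts, function(nuc) {
          w <- v; w[p] <- nuc; paste(w, collapse = "")
        }, character(1))
        alt_aa <- code[alt_codons]
        valid <- alt_aa != "*"
        if (any(valid))
          s <- s + sum(alt_aa[valid] == code[cd]) / sum(valid)
      }
      s
    }, numeric(1))
    .dnds_env$tab <- list(code = code, syn_sites = syn_sites)
    .dnds_env$paths <- new.env(parent = emptyenv())
  }
  .dnds_env$tab
}

## Observed synonymous/non-synonymous differences between two codons,
## averaged over all substitution pathways that avoid stop codons.
codonPathCounts <- function(ca, cb) {
  tab <- codonTable()
  key <- paste(sort(c(ca, cb)), collapse = "|")
  memo <- .dnds_env$paths
  if (!is.null(memo[[key]])) return(memo[[key]])
  va <- strsplit(ca, "")[[1]]; vb <- strsplit(cb, "")[[1]]
  dif <- which(va != vb)
  if (!length(dif)) { memo[[key]] <- c(sd = 0, nd = 0); return(memo[[key]]) }
  perms <- if (length(dif) == 1L) list(dif) else {
    p <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { p[[length(p) + 1L]] <<- prefix; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), dif)
    p
  }
  acc <- c(sd = 0, nd = 0); nvalid <- 0L
  for (path in perms) {
    cur <- va; sd <- 0; nd <- 0; ok <- TRUE
    for (p_ in path) {
      nxt <- cur; nxt[p_] <- vb[p_]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (tab$code[c2] == "*") { ok <- FALSE; break }
      if (tab$code[c1] == tab$code[c2]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + c(sd = sd, nd = nd); nvalid <- nvalid + 1L }
  }
  res <- if (nvalid > 0L) acc / nvalid else c(sd = NA_real_, nd = NA_real_)
  memo[[key]] <- res
  res
}

#' Sitewise dN/dS profile of a codon alignment
#'
#' A counting-based sitewise estimator of the ratio of non-synonymous to
#' synonymous substitution rates. Per codon site, expected synonymous and
#' non-synonymous site counts and observed differences (averaged over
#' stop-free substitution pathways) are pooled over all sequence pairs;
#' proportions are corrected with the Jukes-Cantor formula and the ratio
#' `dN/dS` formed. Uncertainty intervals come from a nonparametric bootstrap
#' at the sequence level: sequences are resampled with replacement and the
#' pooled counts recomputed over all pairs of distinct resampled sequences,
#' which respects the dependence among pairs sharing a sequence (a bootstrap
#' over pairs treats them as independent and yields intervals that are too
#' narrow). A site is flagged *constrained* when the upper interval limit is
#' below 1.
#'
#' Sites with no observed synonymous changes but non-synonymous changes
#' return `Inf` with an `NA` upper bound; sites with no changes at all
#' return `NA` with the widest interval.
#'
#' @param codon_seqs character vector (>= 4) of equal-length, in-frame codon
#'   sequences; gaps `---` allowed, internal stop codons are an error.
#' @param bootstrap_reps bootstrap replicates (default 1000).
#' @param seed optional RNG seed for the bootstrap.
#' @param conf interval coverage (default 0.95).
#' @return data.frame with one row per codon site: `site`, `omega`, `lower`,
#'   `upper`, `n_pairs`, `constrained`.
#' @export
sitewiseDnds <- function(codon_seqs, bootstrap_reps = 1000, seed = NULL,
                         conf = 0.95) {
  if (length(codon_seqs) < 4L) stop("need at least 4 sequences")
  L <- unique(nchar(codon_seqs))
  if (length(L) != 1L || L %% 3L != 0L)
    stop("sequences must be aligned and in frame")
  if (!is.null(seed)) set.seed(seed)
  tab <- codonTable()
  nsites <- L / 3L
  mats <- lapply(codon_seqs, function(s)
    substring(s, 3L * seq_len(nsites) - 2L, 3L * seq_len(nsites)))
  for (m in mats) {
    cod <- m[!grepl("[-N]", m)]
    if (any(tab$code[cod] == "*"))
      stop("internal stop codon in alignment")
  }
  prs <- combn(length(codon_seqs), 2)
  P <- ncol(prs)
  Nd <- Sd <- Ns <- Ss <- matrix(0, P, nsites)
  for (k in seq_len(P)) {
    a <- mats[[prs[1, k]]]; b <- mats[[prs[2, k]]]
    for (s_ in seq_len(nsites)) {
      ca <- a[s_]; cb <- b[s_]
      if (grepl("[-N]", ca) || grepl("[-N]", cb)) next
      cnt <- codonPathCounts(ca, cb)
      if (anyNA(cnt)) next
      syn_a <- tab$syn_sites[ca]; syn_b <- tab$syn_sites[cb]
      Ss[k, s_] <- (syn_a + syn_b) / 2
      Ns[k, s_] <- 3 - Ss[k, s_]
      Sd[k, s_] <- cnt["sd"]; Nd[k, s_] <- cnt["nd"]
    }
  }
  jc <- function(p) {
    out <- rep(Inf, length(p))
    out[is.na(p)] <- NA_real_
    ok <- !is.na(p) & p < 0.75
    out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
    out
  }
  omegaOf <- function(idx) {
    nd <- colSums(Nd[idx, , drop = FALSE]); sd_ <- colSums(Sd[idx, , drop = FALSE])
    nn <- colSums(Ns[idx, , drop = FALSE]); ss <- colSums(Ss[idx, , drop = FALSE])
    dn <- jc(ifelse(nn > 0, nd / nn, NA_real_))
    ds <- jc(ifelse(ss > 0, sd_ / ss, NA_real_))
    w <- dn / ds
    w[nd + sd_ == 0] <- NA_real_                # no changes at all
    w[sd_ == 0 & nd > 0] <- Inf                 # non-synonymous only
    w
  }
  est <- omegaOf(seq_len(P))
  n_seq <- length(codon_seqs)
  ## pair index lookup: pairId[i, j] for i < j
  pairId <- matrix(0L, n_seq, n_seq)
  pairId[cbind(prs[1, ], prs[2, ])] <- seq_len(P)
  boot <- matrix(NA_real_, bootstrap_reps, nsites)
  for (b_ in seq_len(bootstrap_reps)) {
    s <- sample.int(n_seq, n_seq, replace = TRUE)
    sp <- combn(s, 2)
    sp <- sp[, sp[1, ] != sp[2, ], drop = FALSE]  # drop self-pairs
    idx <- pairId[cbind(pmin(sp[1, ], sp[2, ]), pmax(sp[1, ], sp[2, ]))]
    if (length(idx)) boot[b_, ] <- omegaOf(idx)
  }
  alpha <- (1 - conf) / 2
  z <- stats::qnorm(1 - alpha)
  qt <- function(v, q) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    unname(quantile(v, q, type = 1))
  }
  ## normal bootstrap interval on the log scale (ratios are log-symmetric);
  ## the raw percentile interval is the fallback where the point estimate or
  ## the log-scale spread is undefined (zero or infinite ratios)
  lower <- upper <- rep(NA_real_, nsites)
  for (s_ in seq_len(nsites)) {
    lg <- suppressWarnings(log(boot[, s_]))
    lg <- lg[is.finite(lg)]
    if (is.finite(est[s_]) && est[s_] > 0 && length(lg) >= 30) {
      sdl <- sd(lg)
      lower[s_] <- est[s_] * exp(-z * sdl)
      upper[s_] <- est[s_] * exp(z * sdl)
    } else {
      lower[s_] <- qt(boot[, s_], alpha)
      upper[s_] <- qt(boot[, s_], 1 - alpha)
    }
  }
  upper[is.infinite(est)] <- NA_real_
  ## the interval must contain the point estimate
  lower <- pmin(lower, est, na.rm = FALSE)
  upper <- ifelse(is.na(upper), upper, pmax(upper, est))
  data.frame(site = seq_len(nsites), omega = est, lower = lower,
             upper = upper, n_pairs = P,
             constrained = !is.na(upper) & upper < 1)
}
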