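## JTT empirical amino-acid substitution model (Jones, Taylor & Thornton 1992),
## embedded as the published exchangeability lower triangle (column-major,
## ARNDCQEGHILKMFPSTWYV order, as distributed with PAML) and equilibrium
## frequencies. The generator is normalized to one expected substitution per
## site per unit time.

JTT_ORDER <- c("A","R","N","D","C","Q","E","G","H","I",
               "L","K","M","F","P","S","T","W","Y","V")

JTT_EXCH_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9, 11,
  298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70,
  16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33,
  40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14,
  388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16,
  29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQS <- setNames(c(
  0.0767479232521, 0.0516909483091, 0.0426449573550, 0.0515439484561,
  0.0198029801970, 0.0407519592480, 0.0618299381701, 0.0731519268481,
  0.0229439770560, 0.0537609462391, 0.0919039080961, 0.0586759413241,
  0.0238259761740, 0.0401259598740, 0.0509009490991, 0.0687649312351,
  0.0585649414351, 0.0142609857390, 0.0321019678980, 0.0660049339951),
  JTT_ORDER)

## Cache for the eigendecomposition of the normalized generator.
.jtt_env <- new.env(parent = emptyenv())

jttExchangeMatrix <- function() {
  S <- matrix(0, 20, 20, dimnames = list(JTT_ORDER, JTT_ORDER))
  S[lower.tri(S)] <- JTT_EXCH_LOWER
  S + t(S)
}

## Reversible generator Q with Q_ab = S_ab * pi_b, rows summing to zero,
## scaled so that -sum(pi_a Q_aa) = 1 (one expected substitution per unit t).
jttGenerator <- function() {
  S <- jttExchangeMatrix()
  Q <- S * rep(JTT_FREQS, each = 20)
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * JTT_FREQS)
}

jttEigen <- function() {
  if (is.null(.jtt_env$eig)) {
    Q <- jttGenerator()
    d <- sqrt(JTT_FREQS)
    B <- diag(d) %*% Q %*% diag(1 / d)   # symmetric under reversibility
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    .jtt_env$eig <- list(values = e$values,
                         left = diag(1 / d) %*% e$vectors,
                         right = t(e$vectors) %*% diag(d))
  }
  .jtt_env$eig
}

#' Transition probabilities under the JTT model
#'
#' Computes `P(t) = exp(Qt)` for the JTT amino-acid substitution model via the
#' eigendecomposition of the reversible generator. Rows and columns follow the
#' model's `ARNDCQEGHILKMFPSTWYV` order.
#'
#' @param t evolutionary distance in expected substitutions per site.
#' @return 20 x 20 row-stochastic matrix.
#' @export
jttProbMatrix <- function(t) {
  e <- jttEigen()
  P <- e$left %*% (exp(e$values * t) * e$right)
  P[P < 0] <- 0
  dimnames(P) <- list(JTT_ORDER, JTT_ORDER)
  P / rowSums(P)
}

#' JTT equilibrium amino-acid frequencies
#' @return named numeric vector of 20 frequencies.
#' @export
jttFrequencies <- function() JTT_FREQS

#' Log-odds alignment matrix derived from the JTT model
#'
#' Builds an integer substitution matrix in half-bit units,
#' `s(a,b) = round(2 * log2(P(t)[a,b] / pi_b))`, for use with global and local
#' alignment. An `X` row/column with a mildly negative score is appended so
#' sequences containing ambiguous residues remain alignable.
#'
#' @param t evolutionary distance at which odds are evaluated (default 1
#'   substitution/site, a mid-range divergence for paralog comparisons).
#' @return 21 x 21 integer matrix over the 20 amino acids plus `X`.
#' @export
jttLogOddsMatrix <- function(t = 1) {
  P <- jttProbMatrix(t)
  s <- round(2 * log2(P / rep(JTT_FREQS, each = 20)))
  s <- (s + t(s)) / 2   # enforce exact symmetry after rounding
  out <- matrix(-1L, 21, 21, dimnames = list(c(JTT_ORDER, "X"), c(JTT_ORDER, "X")))
  out[1:20, 1:20] <- s
  out
}

#' Maximum likelihood pairwise distance under the JTT model
#'
#' Estimates the evolutionary distance `t` (expected substitutions per site)
#' between two aligned amino-acid sequences by maximizing the likelihood
#' `sum_sites log(pi_a * P(t)[a, b])` under the JTT model. Columns containing
#' gaps (`-`) or unknown residues are excluded. The search is a bracketed
#' scalar optimization over `[1e-6, 10]`; maxima at either bound are reported
#' with a saturation flag.
#'
#' @param a,b aligned amino-acid strings of equal length (may contain `-`).
#' @param tol convergence tolerance of the scalar search.
#' @return list with `distance`, `sites` (gapless columns used) and
#'   `saturated` (TRUE when the optimum lies at a search bound).
#' @export
mlDistance <- function(a, b, tol = 1e-6) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb))
    stop("aligned sequences must have equal length")
  ia <- match(va, JTT_ORDER)
  ib <- match(vb, JTT_ORDER)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep))
    stop("no_overlap: no gapless aligned columns")
  idx <- cbind(ia[keep], ib[keep])
  counts <- table(paste(idx[, 1], idx[, 2]))
  key <- do.call(rbind, lapply(strsplit(names(counts), " "), as.integer))
  n <- as.numeric(counts)
  negll <- function(t) {
    P <- jttProbMatrix(t)
    -sum(n * log(JTT_FREQS[key[, 1]] * pmax(P[key], 1e-300)))
  }
  lower <- 1e-6; upper <- 10
  opt <- optimize(negll, c(lower, upper), tol = tol)
  t_hat <- opt$minimum
  ## optimize never returns the exact bounds; snap and flag when the
  ## likelihood keeps improving towards a bound.
  saturated <- FALSE
  if (negll(lower) <= opt$objective) { t_hat <- lower; saturated <- TRUE }
  if (negll(upper) <= opt$objective) { t_hat <- upper; saturated <- TRUE }
  list(distance = t_hat, sites = sum(keep), saturated = saturated)
}

#' Evolve an amino-acid sequence under the JTT model
#'
#' Substitutes residues of `aa` according to `P(t)` under the JTT model. Used
#' by the synthetic-data generator; positions with non-standard letters are
#' left unchanged.
#'
#' @param aa amino-acid string.
#' @param t branch length in expected substitutions per site.
#' @return the evolved amino-acid string.
#' @export
evolveAASequence <- function(aa, t) {
  v <- strsplit(aa, "")[[1]]
  idx <- match(v, JTT_ORDER)
  ok <- which(!is.na(idx))
  if (length(ok) == 0L || t <= 0) return(aa)
  P <- jttProbMatrix(t)
  for (a in unique(idx[ok])) {
    pos <- ok[idx[ok] == a]
    v[pos] <- sample(JTT_ORDER, length(pos), replace = TRUE, prob = P[a, ])
  }
  paste(v, collapse = "")
}
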