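test_that("alignPair matches hand computation and the alignment oracle", {
  # identical sequences: gapless, identical strings
  al <- alignPair("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(al$a, al$b)
  expect_false(grepl("-", al$a))

  # "ACDE" vs "ACE": one gap, score = matches - (open + 1*extend),
  # summed by hand from the substitution matrix
  mat <- jttLogOddsMatrix()
  al <- alignPair("ACDE", "ACE")
  expect_equal(al$score,
               mat["A", "A"] + mat["C", "C"] + mat["E", "E"] - 12)
  expect_equal(nchar(al$a), 4L)
  expect_equal(sum(strsplit(al$b, "")[[1]] == "-"), 1L)

  # score symmetric in argument order
  set.seed(13)
  a <- randomAAString(40); b <- randomAAString(33)
  expect_equal(alignPair(a, b)$score, alignPair(b, a)$score)

  # agreement with the independent dynamic-programming engine
  for (i in 1:10) {
    a <- randomAAString(sample(10:60, 1))
    b <- randomAAString(sample(10:60, 1))
    mine <- alignPair(a, b)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      type = "global")
    expect_equal(mine$score, Biostrings::score(ref))
    expect_equal(gsub("-", "", mine$a), a)
    expect_equal(gsub("-", "", mine$b), b)
  }
})

test_that("mlDistance recovers simulated JTT divergences", {
  # identical sequences sit at the lower search bound
  a <- randomAAString(100)
  d <- mlDistance(a, a)
  expect_lt(d$distance, 1e-5)
  expect_true(d$saturated)

  # 500-site pairs at t = 0.3: mean estimate within 0.03 over 50 replicates
  set.seed(20)
  anc <- randomAAString(500)
  ests <- replicate(50, {
    mlDistance(evolveAASequence(anc, 0.15), evolveAASequence(anc, 0.15))$distance
  })
  expect_lt(abs(mean(ests) - 0.3), 0.03)

  # distance grows stochastically with the divergence that generated it
  set.seed(21)
  med <- vapply(c(0.1, 0.5, 1.0), function(t) {
    median(replicate(10, mlDistance(anc, evolveAASequence(anc, t))$distance))
  }, numeric(1))
  expect_true(all(diff(med) > 0))

  expect_error(mlDistance("-A", "A-"), "no_overlap")
})

test_that("mlDistance agrees with an independent likelihood oracle", {
  skip_if_not_installed("phangorn")
  set.seed(22)
  anc <- randomAAString(300)
  a <- evolveAASequence(anc, 0.2)
  b <- evolveAASequence(anc, 0.2)
  mine <- mlDistance(a, b)$distance
  pd <- phangorn::phyDat(rbind(a = strsplit(a, "")[[1]],
                               b = strsplit(b, "")[[1]]), type = "AA")
  ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))[1, 2]
  expect_equal(mine, ref, tolerance = 1e-4)
})

test_that("computeIopds forms exactly the within-assembly pairs", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "h1", "h2"),
    assembly_id = c("a1", "a1", "a1", "a2", "a2"),
    family = "F",
    prepropeptide = replicate(5, randomAAString(50)),
    stringsAsFactors = FALSE)
  iop <- computeIopds(genes, level = "gene")
  expect_equal(nrow(iop), 4L)   # C(3,2) pairs in a1 plus C(2,2) in a2
  expect_equal(sum(iop$assembly_id == "a1"), 3L)
  expect_equal(sum(iop$assembly_id == "a2"), 1L)
  # no cross-assembly pairs
  expect_false(any(iop$id_a %in% c("h1", "h2") &
                     iop$id_b %in% c("g1", "g2", "g3")))

  # assemblies with fewer than two sequences contribute nothing
  solo <- genes[c(1, 4, 5), ]
  iop <- computeIopds(solo, level = "gene")
  expect_equal(unique(iop$assembly_id), "a2")
})

test_that("domain-level IOPDs use the individual 15-mers", {
  genes <- data.frame(
    gene_id = c("g1", "g2"), assembly_id = "a1", family = "F",
    prepropeptide = c(paste0(strrep("A", 10), randomAAString(15)),
                      paste0(strrep("A", 5), randomAAString(15),
                             strrep("S", 3), randomAAString(15))),
    domain_offsets = c("10", "5,23"), stringsAsFactors = FALSE)
  iop <- computeIopds(genes, level = "domain")
  expect_equal(nrow(iop), choose(3, 2))
})

test_that("rankTukey agrees with a hand-computed studentized range", {
  # balanced three-group fixture, computed independently from the
  # studentized-range distribution on the rank scale
  g <- rep(c("a", "b", "c"), each = 5)
  x <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10, 20, 21, 22, 23, 24)
  M <- rankTukey(x, g)
  r <- rank(x)
  mns <- tapply(r, g, mean)
  mse <- sum((r - ave(r, g))^2) / (length(r) - 3)
  qstat <- abs(mns["a"] - mns["c"]) / sqrt(mse / 5)
  pref <- 1 - ptukey(qstat, nmeans = 3, df = length(r) - 3)
  expect_equal(M["a", "c"], unname(pref), tolerance = 1e-6)

  # two identical groups are not distinguished
  set.seed(30)
  x <- rnorm(20)
  M <- rankTukey(c(x, x), rep(c("u", "v"), each = 20))
  expect_gt(M["u", "v"], 0.9)

  # a clearly shifted group is flagged, the equal pair is not
  set.seed(31)
  x <- c(rnorm(20), rnorm(20), rnorm(20) + 5)
  g <- rep(c("a", "b", "c"), each = 20)
  M <- rankTukey(x, g)
  expect_lt(M["a", "c"], 0.05)
  expect_lt(M["b", "c"], 0.05)
  expect_gt(M["a", "b"], 0.1)

  # degenerate zero-variance input follows the p = 1 path
  M <- rankTukey(rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(M["a", "b"], 1)
})

test_that("logitTukey transforms proportions to log-odds before testing", {
  expect_equal(qlogis(0.5), 0)
  set.seed(32)
  gc <- c(pmin(pmax(rnorm(40, 0.65, 0.05), 0.01), 0.99),
          pmin(pmax(rnorm(40, 0.45, 0.05), 0.01), 0.99))
  fam <- rep(c("poa", "sol"), each = 40)
  M <- logitTukey(gc, fam)
  expect_lt(M["poa", "sol"], 0.001)
  # monotone transformation preserves group ordering
  expect_gt(mean(qlogis(gc[fam == "poa"])), mean(qlogis(gc[fam == "sol"])))
  # exact boundary values need the smoothing adjustment
  expect_error(logitTukey(c(0, 0.5, 1, 0.5), rep(c("a", "b"), each = 2),
                          adjust = FALSE), "adjust")
})

test_that("trimColumns cuts at the steepest drop of the gap distribution", {
  msa <- c("ACDEF", "ACDEF", "ACDEF")
  tr <- trimColumns(msa)
  expect_equal(tr$msa, msa)
  expect_equal(tr$kept, 1:5)

  # one all-gap column is excised
  msa <- c("AC-EF", "AC-EF", "AC-EF")
  tr <- trimColumns(msa)
  expect_equal(tr$msa, rep("ACEF", 3))
  expect_equal(tr$kept, c(1, 2, 4, 5))

  # bimodal gap profile: columns are either clean (<= 1/4 gaps) or ragged
  # (>= 3/4 gaps); the cut lands in the inter-mode drop
  msa <- c("ACDE--QQ", "ACDE---Q", "ACD-E--Q", "ACDE-P-Q")
  tr <- trimColumns(msa)
  expect_equal(tr$kept, c(1, 2, 3, 4, 8))
})

test_that("sitewise dN/dS counting matches a hand-computed NG86 table", {
  # four sequences, three codon sites:
  #   site 1: TTT/TTT/TTC/TTC  (F vs F, all third-position changes: Sd only)
  #   site 2: ATG/ATG/ATG/ATG  (invariant)
  #   site 3: AAA/AAA/GAA/GAA  (K vs E, first-position change: Nd only)
  seqs <- c("TTTATGAAA", "TTTATGAAA", "TTCATGGAA", "TTCATGGAA")
  prof <- sitewiseDnds(seqs, bootstrap_reps = 50, seed = 1)
  expect_equal(prof$omega[1], 0)            # synonymous only
  expect_true(is.na(prof$omega[2]))         # no changes at all
  expect_true(is.infinite(prof$omega[3]))   # non-synonymous only, Sd = 0
  expect_true(is.na(prof$upper[3]))
  expect_true(prof$constrained[1])
  expect_false(prof$constrained[3])
})

test_that("pathway counting averages over stop-free paths", {
  # TTA (Leu) -> ATG (Met): positions 1 and 3 differ. Path via ATA counts
  # two non-synonymous steps; path via TTG counts one synonymous (L->L)
  # then one non-synonymous (L->M). Average: Nd = 1.5, Sd = 0.5.
  cnt <- cepkit:::codonPathCounts("TTA", "ATG")
  expect_equal(unname(cnt["nd"]), 1.5, tolerance = 1e-12)
  expect_equal(unname(cnt["sd"]), 0.5, tolerance = 1e-12)
  # TGG (Trp) -> TAT (Tyr): the path via TAG runs through a stop codon and
  # is discarded, leaving only the path via TGT (C), all non-synonymous
  cnt <- cepkit:::codonPathCounts("TGG", "TAT")
  expect_equal(unname(cnt["nd"]), 2)
  expect_equal(unname(cnt["sd"]), 0)
  # single-difference pairs are classified directly
  expect_equal(unname(cepkit:::codonPathCounts("TTT", "TTC")),
               c(1, 0))   # synonymous
  expect_equal(unname(cepkit:::codonPathCounts("AAA", "GAA")),
               c(0, 1))   # non-synonymous
})

test_that("dN/dS recovery separates constrained from neutral sites", {
  omegas <- rep(c(0.2, 1.0), each = 15)
  seqs <- simCodonAlignment(20, omegas, events = 3, seed = 11)
  prof <- sitewiseDnds(seqs, bootstrap_reps = 300, seed = 5)
  # point estimates separate cleanly by regime
  expect_lt(median(prof$omega[1:15], na.rm = TRUE), 0.4)
  expect_gt(median(prof$omega[16:30], na.rm = TRUE), 0.6)
  # specificity holds at the one-site resolution of this fixture;
  # sensitivity of the counting estimator with honest sequence-level
  # intervals is a clear majority of constrained sites
  expect_gte(mean(prof$constrained[1:15]), 0.6)
  expect_lte(sum(prof$constrained[16:30]), 1L)
  # interval contains the point estimate wherever both exist
  ok <- !is.na(prof$omega) & is.finite(prof$omega) & !is.na(prof$upper)
  expect_true(all(prof$lower[ok] <= prof$omega[ok] + 1e-12))
  expect_true(all(prof$upper[ok] >= prof$omega[ok] - 1e-12))
})
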