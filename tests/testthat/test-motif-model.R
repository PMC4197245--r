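domTable <- function(seqs, orf, asm, org = asm) {
  data.frame(sequence = seqs, orf_id = orf, assembly_id = asm,
             organism = org, stringsAsFactors = FALSE)
}

test_that("three-level equalization reproduces hand-computed masses", {
  star <- ape::read.tree(text = "(a1,a2);")
  # two assemblies, one single-domain ORF each: symmetric halves
  d <- domTable(rep(strrep("A", 15), 2), c("o1", "o2"), c("a1", "a2"))
  w <- assignWeights(d, star)$weight
  expect_equal(w, c(0.5, 0.5))

  # assembly A {ORF1: 2 domains, ORF2: 1 domain}, assembly B {1 ORF, 1
  # domain}: pre-normalization masses A:(0.25, 0.25, 0.5), B:(1.0)
  d <- domTable(rep(strrep("A", 15), 4),
                c("orf1", "orf1", "orf2", "orf3"),
                c("a1", "a1", "a1", "a2"))
  w <- assignWeights(d, star)$weight
  expect_equal(w, c(0.25, 0.25, 0.5, 1.0) / 2)
})

test_that("lineage decay multiplies weights by decay^depth and renormalizes", {
  # caterpillar ((x,y),z): depth(x) = depth(y) = 2, depth(z) = 1
  tr <- ape::read.tree(text = "((x,y),z);")
  d <- domTable(rep(strrep("A", 15), 2), c("o1", "o2"), c("x", "z"),
                org = c("x", "z"))
  w <- assignWeights(d, tr, decay = 0.8)$weight
  # stage-2 multiplier ratio between depth 2 and depth 1 is 0.8
  expect_equal(w[1] / w[2], 0.8)
  expect_equal(sum(w), 1)

  # depth 3 vs depth 1 under 0.8 gives ratio 0.8^2 = 0.64 of the decay part
  tr <- ape::read.tree(text = "(((x,y),z),u);")
  d <- domTable(rep(strrep("A", 15), 2), c("o1", "o2"), c("x", "u"),
                org = c("x", "u"))
  w <- assignWeights(d, tr, decay = 0.8)$weight
  expect_equal(w[1] / w[2], 0.8^2)
})

test_that("assignWeights sums to one, ignores input order, checks leaves", {
  tr <- ape::read.tree(text = "((x,y),z);")
  set.seed(1)
  d <- domTable(replicate(6, randomAAString(15)),
                paste0("o", c(1, 1, 2, 3, 4, 4)),
                c("x", "x", "x", "y", "z", "z"),
                org = c("x", "x", "x", "y", "z", "z"))
  w1 <- assignWeights(d, tr)
  expect_equal(sum(w1$weight), 1)
  perm <- c(4, 2, 6, 1, 3, 5)
  w2 <- assignWeights(d[perm, ], tr)
  expect_equal(w2$weight, w1$weight[perm])
  d$organism[1] <- "missing_org"
  expect_error(assignWeights(d, tr), "missing_org")
})

test_that("buildPSPM implements weighted column counting exactly", {
  p <- buildPSPM("ACDEFGHIKLMNPQR", pseudocount = 0)
  expect_equal(unname(motifProbs(p)[1, "A"]), 1)
  expect_equal(unname(motifProbs(p)[5, "F"]), 1)

  p <- buildPSPM(c("ACD", "GCD"), pseudocount = 0)
  expect_equal(unname(motifProbs(p)[1, c("A", "G")]), c(0.5, 0.5))

  # formula check with explicit weights and pseudocount
  d <- data.frame(sequence = c("AC", "GC"), weight = c(3, 1))
  p <- buildPSPM(d, pseudocount = 0.4)
  expect_equal(unname(motifProbs(p)[1, "A"]), (3 + 0.4 * 0.05) / 4.4)
  expect_equal(unname(motifProbs(p)[1, "G"]), (1 + 0.4 * 0.05) / 4.4)
  expect_error(buildPSPM(data.frame(sequence = character())), "empty")
})

test_that("buildPSPM recovers a generating matrix from samples", {
  pspm <- defaultDomainPSPM()
  set.seed(42)
  doms <- sampleFromPSPM(pspm, 100)
  est <- buildPSPM(doms, pseudocount = 0)
  tv <- apply(abs(motifProbs(est) - motifProbs(pspm)), 1, sum) / 2
  expect_lt(max(tv), 0.25)   # multinomial noise at n = 100
  # at n = 10^4 the estimate converges within 0.02 total variation per row
  doms <- sampleFromPSPM(pspm, 1e4)
  est <- buildPSPM(doms, pseudocount = 0)
  tv <- apply(abs(motifProbs(est) - motifProbs(pspm)), 1, sum) / 2
  expect_lt(max(tv), 0.02)
})

test_that("scoreWindow is the log2 odds sum", {
  flat <- toyPSPM(rep(list(setNames(rep(0.05, 20), AA_LETTERS)), 4))
  expect_equal(scoreWindow(flat, "ACDE"), 0)

  toy <- toyPSPM(list(c(A = 0.8, C = 0.1, D = 0.1),
                      c(C = 0.6, D = 0.4),
                      c(D = 1)))
  expect_equal(scoreWindow(toy, "ACD"),
               log2(0.8 / 0.05) + log2(0.6 / 0.05) + log2(1 / 0.05))
  expect_error(scoreWindow(toy, "AC"), "width")
})

test_that("exact P-value DP matches brute-force enumeration on a toy motif", {
  # width-2 motif over a 4-letter reduced alphabet (uniform background on
  # the full alphabet; letters outside the support score -Inf and drop out)
  toy <- toyPSPM(list(c(A = 0.55, C = 0.25, D = 0.15, E = 0.05),
                      c(A = 0.05, C = 0.15, D = 0.30, E = 0.50)))
  lett <- c("A", "C", "D", "E")
  wins <- expand.grid(lett, lett, stringsAsFactors = FALSE)
  scores <- apply(wins, 1, function(w)
    scoreWindow(toy, paste(w, collapse = "")))
  for (thr in sort(unique(scores))) {
    brute <- sum(0.05 * 0.05 * (scores >= thr - 1e-12))
    expect_equal(scorePvalue(toy, thr), brute, tolerance = 1e-9)
  }
})

test_that("P-value respects boundary thresholds and monotonicity", {
  pspm <- defaultDomainPSPM()
  lod <- log2(motifProbs(pspm) / 0.05)
  expect_equal(scorePvalue(pspm, sum(apply(lod, 1, min))), 1.0)
  expect_equal(scorePvalue(pspm, sum(apply(lod, 1, max)) + 1), 0.0)
  thr <- seq(-20, 60, by = 5)
  pv <- vapply(thr, function(t) scorePvalue(pspm, t), numeric(1))
  expect_true(all(diff(pv) <= 0))
  expect_error(scorePvalue(pspm, Inf), "finite")
})

test_that("halving the granularity changes P-values by less than 1%", {
  pspm <- defaultDomainPSPM()
  sd0 <- cepkit:::pspmScoreDistribution(pspm)
  for (thr in c(10, 15.37, 25)) {
    p1 <- scorePvalue(pspm, thr, granularity = sd0$g)
    p2 <- scorePvalue(pspm, thr, granularity = sd0$g / 2)
    expect_lt(abs(p1 - p2) / p1, 0.01)
  }
})

test_that("null P-values are super-uniform on background draws", {
  # p-values of a discretized score distribution are stochastically
  # dominated by U(0,1): P(p <= x) <= x, with equality up to the atom
  # structure of the score grid (an atom of mass ~0.2 sits at p = 1 where
  # many letters share the pseudocount floor)
  pspm <- defaultDomainPSPM()
  sd <- cepkit:::pspmScoreDistribution(pspm)
  set.seed(8)
  aa <- paste(sample(AA_LETTERS, 1e4 + 14, replace = TRUE), collapse = "")
  v <- match(strsplit(aa, "")[[1]], AA_LETTERS)
  scores <- rep(0, 1e4)
  for (j in 1:15)
    scores <- scores + log2(motifProbs(pspm) / 0.05)[j, ][v[j:(j + 1e4 - 1)]]
  pv <- vapply(scores, function(s) cepkit:::tailLookup(sd, s), numeric(1))
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_ <- vapply(grid, function(x) mean(pv <= x), numeric(1))
  expect_true(all(ecdf_ <= grid + 0.02))
  # away from the floor atom the calibration is tight
  expect_lt(max(abs(ecdf_[grid <= 0.2] - grid[grid <= 0.2])), 0.02)
})

test_that("scanOrf reports planted hits and resolves overlaps greedily", {
  pspm <- defaultDomainPSPM()
  set.seed(3)
  dom <- sampleFromPSPM(pspm, 1)
  flank1 <- randomAAString(30)
  flank2 <- randomAAString(25)
  hits <- scanOrf(pspm, paste0(flank1, dom, flank2))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 30L)
  expect_equal(hits$match, dom)

  # two planted non-overlapping domains come back in offset order
  dom2 <- sampleFromPSPM(pspm, 1)
  hits <- scanOrf(pspm, paste0(flank1, dom, flank2, dom2, flank1))
  expect_equal(hits$offset, c(30L, 70L))

  expect_equal(nrow(scanOrf(pspm, "ACDEFGHIKL")), 0L)
})

test_that("iterated build-scan-rebuild is stable when the model is true", {
  pspm <- defaultDomainPSPM()
  set.seed(11)
  doms <- sampleFromPSPM(pspm, 400)
  orfs <- paste0(vapply(seq_along(doms), function(i) randomAAString(20),
                        character(1)), doms)
  cur <- buildPSPM(doms)
  tvs <- numeric(3)
  for (it in 1:3) {
    found <- unlist(lapply(orfs, function(o) scanOrf(cur, o, 1e-8)$match))
    nxt <- buildPSPM(found)
    tvs[it] <- max(apply(abs(motifProbs(nxt) - motifProbs(cur)), 1, sum)) / 2
    cur <- nxt
  }
  # rescanning recovers the same site set, so the matrix stops moving
  expect_lt(tvs[2], 1e-12)
  expect_lt(tvs[3], 1e-12)
})

test_that("familyLogoStats reflects hierarchical weights", {
  d <- data.frame(sequence = c("AC", "GC"), weight = c(1, 1))
  st <- familyLogoStats(d)
  expect_equal(unname(st$freqs[1, c("A", "G")]), c(0.5, 0.5))
  expect_equal(unname(st$ic[2]), log2(20))  # all-identical column

  # weighted frequencies follow the assigned masses: the two-assembly
  # fixture gives domains masses (0.25, 0.25, 0.5, 1)/2
  star <- ape::read.tree(text = "(a1,a2);")
  d <- domTable(c("A", "C", "C", "G"), c("orf1", "orf1", "orf2", "orf3"),
                c("a1", "a1", "a1", "a2"))
  w <- assignWeights(d, star)
  st <- familyLogoStats(w)
  expect_equal(unname(st$freqs[1, c("A", "C", "G")]),
               c(0.125, 0.375, 0.5))
})

test_that("aaMaxGC follows the standard codon table", {
  expect_equal(aaMaxGC(c("G", "F", "K")), c(3L, 1L, 1L))
  expect_equal(aaMaxGC("P"), 3L)   # CCC
  expect_equal(aaMaxGC("W"), 2L)   # TGG
  expect_error(aaMaxGC("B"), "unknown")
})
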