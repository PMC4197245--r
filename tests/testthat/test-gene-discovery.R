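test_that("extractOrfs finds maximal stop-free runs in all six frames", {
  # a 153-nt stop-free contig (repeating GCT is stop-free in all six
  # frames: Ala/Leu/Cys forward, Ser/Ala/Gln on the reverse strand) yields
  # runs of 51/50/50 aa per strand; all runs >= 50 are emitted
  nt <- strrep("GCT", 51)
  asm <- GenomeAssembly(setNames(nt, "c1"), "a1")
  orfs <- extractOrfs(asm, min_orf_len = 50)
  expect_equal(nrow(orfs), 6L)
  expect_setequal(orfs$aa_len[orfs$strand == "+"], c(51L, 50L, 50L))
  expect_false(any(orfs$has_stop))

  # every reported ORF retranslates from its forward-strand span
  for (i in seq_len(nrow(orfs))) {
    span <- Biostrings::DNAString(substr(nt, orfs$start[i] + 1, orfs$end[i]))
    if (orfs$strand[i] == "-") span <- Biostrings::reverseComplement(span)
    expect_equal(as.character(Biostrings::translate(span)), orfs$aa[i])
  }
})

test_that("the 50-aa boundary is inclusive and stops bound runs", {
  set.seed(4)
  body <- backTranslate(paste0("M", randomAAString(49)))
  nt <- paste0(body, "TAA")
  asm <- GenomeAssembly(setNames(nt, "c1"), "a1")
  orfs <- extractOrfs(asm, min_orf_len = 50)
  fwd0 <- orfs[orfs$strand == "+" & orfs$frame == 0, ]
  expect_equal(nrow(fwd0), 1L)
  expect_equal(fwd0$aa_len, 50L)
  expect_true(fwd0$has_stop)
  longer <- extractOrfs(asm, min_orf_len = 51)
  expect_equal(sum(longer$strand == "+" & longer$frame == 0), 0L)
})

test_that("N codons translate to X and do not terminate a run", {
  set.seed(6)
  aa <- paste0("M", randomAAString(60))
  nt <- paste0(backTranslate(aa), "TAA")
  substr(nt, 31, 33) <- "NNN"
  asm <- GenomeAssembly(setNames(nt, "c1"), "a1")
  orfs <- extractOrfs(asm)
  f0 <- orfs[orfs$strand == "+" & orfs$frame == 0, ]
  expect_equal(f0$aa_len, 61L)
  expect_equal(substr(f0$aa, 11, 11), "X")
})

test_that("heuristic signal scorer matches its documented formula", {
  scorer <- heuristicSignalScorer()
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  # strong signal: charged n-region, leucine core, A-x-A cleavage box
  prefix <- paste0("MKK", strrep("L", 12), "AQA", "SSTT")
  # independent evaluation of the published feature recipe
  v <- strsplit(prefix, "")[[1]]
  charge <- sum(v[2:5] %in% c("K", "R"))
  hyd <- max(vapply(6:13, function(i) mean(kd[v[i:(i + 7)]]), numeric(1)))
  expected <- plogis(1.2 * min(charge, 2) + 0.9 * (hyd - 1.5) + 1.4 * 2 - 3.2)
  expect_equal(signalScore(scorer, prefix), expected)
  expect_gt(signalScore(scorer, prefix), 0.8)
  expect_equal(cleavageSite(scorer, prefix), 18L)

  expect_lt(signalScore(scorer, strrep("D", 30)), 0.1)
  expect_equal(signalScore(scorer, "MKL"), 0)   # shorter than 15 residues
  # purity
  expect_identical(signalScore(scorer, prefix), signalScore(scorer, prefix))
})

test_that("findStart picks the maximum-scoring candidate above the cutoff", {
  aa <- paste0("M", strrep("A", 9), "L", strrep("A", 19), strrep("G", 15))
  nt <- backTranslate(aa)
  lut <- data.frame(prefix = c(substring(aa, 1), substring(aa, 11)),
                    score = c(0.6, 0.9), cleavage = c(20L, 16L))
  scorer <- tableSignalScorer(lut)
  fs <- findStart(aa, nt, first_domain_offset = 30L, scorer)
  expect_equal(fs$start, 10L)       # the 0.9-scoring leucine start
  expect_equal(fs$score, 0.9)
  expect_equal(fs$nss_len, 16L)

  # all candidates at or below 0.400 (strictly-greater rule) are rejected
  lut$score <- c(0.400, 0.35)
  fs <- findStart(aa, nt, 30L, tableSignalScorer(lut))
  expect_true(fs$rejected)
  expect_equal(fs$reason, "no_signal")

  # ties break to the 5'-most candidate
  lut$score <- c(0.7, 0.7)
  fs <- findStart(aa, nt, 30L, tableSignalScorer(lut))
  expect_equal(fs$start, 0L)

  # no candidate codons at all
  aa2 <- paste0(strrep("G", 20), strrep("A", 15))
  fs <- findStart(aa2, backTranslate(aa2), 20L, scorer)
  expect_equal(fs$reason, "no_start")
})

test_that("parseArchitecture tiles the prepropeptide exactly", {
  # the canonical 19/10/15/4 segmentation of a 48-residue gene
  orf <- list(aa = paste0(strrep("A", 19), strrep("V", 10), strrep("G", 15),
                          strrep("S", 4)),
              has_stop = TRUE)
  hits <- data.frame(offset = 29L)
  arch <- parseArchitecture(orf, start = 0L, nss_len = 19L, hits = hits)
  expect_equal(nchar(arch$prepropeptide), 48L)
  expect_equal(arch$var_len, 10L)
  expect_equal(arch$cterm_len, 4L)
  expect_false(arch$no_cterm)

  # stop codon immediately after the domain: zero-length extension, flagged
  orf$aa <- paste0(strrep("A", 19), strrep("V", 10), strrep("G", 15))
  arch <- parseArchitecture(orf, 0L, 19L, data.frame(offset = 29L))
  expect_equal(arch$cterm_len, 0L)
  expect_true(arch$no_cterm)

  # two domains with a 7-residue spacer: offsets differ by 22
  orf$aa <- paste0(strrep("A", 19), strrep("V", 10), strrep("G", 15),
                   strrep("P", 7), strrep("H", 15), "SS")
  arch <- parseArchitecture(orf, 0L, 19L, data.frame(offset = c(29L, 51L)))
  expect_equal(diff(arch$domain_offsets), 22L)
  expect_equal(arch$spacer_total, 7L)

  # a domain overlapping the signal region is a rejection
  arch <- parseArchitecture(orf, 0L, 35L, data.frame(offset = 29L))
  expect_equal(arch$reason, "domain_in_signal")
  # no bounding stop codon: the C-terminal border is undefined
  orf$has_stop <- FALSE
  arch <- parseArchitecture(orf, 0L, 19L, data.frame(offset = 29L))
  expect_equal(arch$reason, "no_stop")
})

test_that("gcContent excludes N from numerator and denominator", {
  expect_equal(gcContent(c("GCGC", "ATAT", "ATGC")), c(1, 0, 0.5))
  expect_equal(gcContent("GCNN"), 1)
  expect_true(is.na(gcContent("NNNN")))
  expect_error(gcContent(""), "empty")
})

test_that("discovered genes retranslate and empty assemblies yield nothing", {
  ds <- simulateDataset(simConfig(seed = 31, n_species = 2,
                                  n_ortholog_sets = 3))
  genes <- discoverGenes(ds$assemblies[[1]], ds$pspm)
  expect_gt(nrow(genes), 0)
  for (i in seq_len(nrow(genes))) {
    expect_equal(as.character(Biostrings::translate(
      Biostrings::DNAString(genes$cds[i]))), genes$prepropeptide[i])
  }
  empty <- GenomeAssembly(setNames(randomBg(200), "c1"), "e1")
  expect_equal(nrow(discoverGenes(empty, ds$pspm)), 0L)
})

test_that("discovery is strand-symmetric", {
  ds <- simulateDataset(simConfig(seed = 32, n_species = 2,
                                  n_ortholog_sets = 3))
  asm <- ds$assemblies[[1]]
  genes <- discoverGenes(asm, ds$pspm)
  flipped <- GenomeAssembly(Biostrings::reverseComplement(contigs(asm)),
                            assemblyId(asm), organism(asm))
  names(flipped@sequences) <- names(contigs(asm))
  genes2 <- discoverGenes(flipped, ds$pspm)
  expect_equal(nrow(genes2), nrow(genes))
  L <- Biostrings::width(contigs(asm))[1]
  key1 <- paste(genes$strand, genes$cds_start, genes$cds_end)
  key2 <- paste(ifelse(genes2$strand == "+", "-", "+"),
                L - genes2$cds_end, L - genes2$cds_start)
  expect_setequal(key1, key2)
  expect_setequal(genes$prepropeptide, genes2$prepropeptide)
})
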