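## Synthetic genomes, species trees, gene families and truth tables with the
## statistical structure the discovery pipeline assumes: single-exon genes
## (secretion signal + variable region + one or more 15-residue domains + an
## optional short C-terminal extension) embedded on both strands of random
## intergenic background, alongside three decoy classes (diverged "group
## II"-like domains, domains without a signal, signals without a domain).
## All randomness flows from the single seed in the configuration.

## Synthetic seed set of canonical-style 15-mer domains used to build the
## default generating matrix: a conserved C-terminal block (positions 7-15)
## with a more variable N-terminal half, mirroring the family's consensus
## structure.
DOMAIN_SEED_SET <- c(
  "DFRPTNPGHSPGVGH", "DFRPTEPGHSPGVGH", "AFQPTTPGHSPGVGH",
  "DFRPTTPGHSPGIGH", "GFRPTAPGHSPGVGH", "DFQPTSPGHSPGIGH",
  "DLRPTNPGHSPGVGH", "DFRPTAPGHSPGVGH", "EFRPTSPGHSPGVGH",
  "DFRPTNSGHSPGVGH", "DYRPTNPGHSPGVGH", "DFRPSNPGHSPGVGH")

#' Default generating PSPM for the synthetic-data module
#'
#' Built from a small synthetic seed set of canonical-style domains with the
#' standard pseudocount smoothing. Sequences sampled from this matrix score
#' far above the survey's scan threshold, so rejection sampling in the
#' generator almost never loops.
#' @return a [PSPM-class].
#' @export
defaultDomainPSPM <- function() {
  buildPSPM(DOMAIN_SEED_SET, motifId = "synthetic-canonical-domain")
}

#' Sample sequences from a PSPM
#'
#' @param pspm a [PSPM-class].
#' @param n number of sequences.
#' @return character vector of length `n`.
#' @export
sampleFromPSPM <- function(pspm, n = 1) {
  p <- motifProbs(pspm)
  vapply(seq_len(n), function(i)
    paste(vapply(seq_len(nrow(p)), function(j)
      sample(AA20, 1, prob = p[j, ]), character(1)), collapse = ""),
    character(1))
}

## Column-rotated, uniform-mixed variant of a PSPM: still motif-like but
## diverged, used to draw "group II"-style decoy domains.
perturbPSPM <- function(pspm, mix = 0.4, shift = 3L) {
  p <- motifProbs(pspm)
  w <- nrow(p)
  p2 <- p[((seq_len(w) - 1L + shift) %% w) + 1L, , drop = FALSE]
  p2 <- (1 - mix) * p2 + mix / 20
  new("PSPM", motifId = paste0(motifId(pspm), "-perturbed"), probs = p2,
      background = motifBackground(pspm), pseudocount = pspm@pseudocount,
      nsites = pspm@nsites)
}

## Residues that carry neither positive charge, hydrophobic bulk, Met/Leu
## start candidates nor cleavage-like smallness; used for signal-less decoys.
SAFE_NO_SIGNAL_AA <- c("D", "E", "N", "Q", "P", "H")

#' Generate an N-terminal secretion-signal template
#'
#' Templates follow the classical tripartite layout: `M` + two positively
#' charged residues, a hydrophobic h-region of 10-12 residues from
#' `{L,I,V,F}`, and an `A-x-A` cleavage box. Templates are rejection-sampled
#' to score above `min_score` under [heuristicSignalScorer()] so signal
#' detection is not the recovery bottleneck in default suites.
#'
#' @param min_score minimum heuristic signal score (default 0.8).
#' @return list with `aa` (the template) and `nss_len` (its length, which is
#'   also the scorer's cleavage call).
#' @export
nssTemplate <- function(min_score = 0.8) {
  scorer <- heuristicSignalScorer()
  for (i in seq_len(1000)) {
    aa <- paste0("M", paste(sample(c("K", "R"), 2, replace = TRUE), collapse = ""),
                 paste(sample(c("L", "I", "V", "F"), sample(10:12, 1),
                              replace = TRUE), collapse = ""),
                 "A", sample(c("Q", "E", "N"), 1), "A")
    if (signalScore(scorer, aa) > min_score &&
        cleavageSite(scorer, aa) == nchar(aa))
      return(list(aa = aa, nss_len = nchar(aa)))
  }
  stop("could not generate a signal template above the score floor")
}

## Codon families per amino acid, stops excluded.
.codon_env <- new.env(parent = emptyenv())
codonsByAA <- function() {
  if (is.null(.codon_env$by_aa)) {
    code <- Biostrings::GENETIC_CODE
    .codon_env$by_aa <- split(names(code), unname(code))
    .codon_env$gc_count <- vapply(strsplit(names(code), ""), function(x)
      sum(x %in% c("G", "C")), integer(1)) |> setNames(names(code))
  }
  .codon_env
}

#' Back-translate an amino-acid sequence
#'
#' Chooses a codon for every residue; with `gc3_bias = 0` codons are drawn
#' uniformly within each synonymous family, positive values weight codons by
#' `exp(gc3_bias * GC-count)`, emulating GC-biased codon usage.
#'
#' @param aa amino-acid string (no gaps).
#' @param gc3_bias GC preference strength (0 = uniform codon usage).
#' @return nucleotide string of length `3 * nchar(aa)`.
#' @export
backTranslate <- function(aa, gc3_bias = 0) {
  env <- codonsByAA()
  v <- strsplit(aa, "")[[1]]
  out <- character(length(v))
  for (a in unique(v)) {
    cods <- env$by_aa[[a]]
    if (is.null(cods)) stop("cannot back-translate residue: ", a)
    pos <- which(v == a)
    out[pos] <- if (length(cods) == 1L) cods else
      sample(cods, length(pos), replace = TRUE,
             prob = exp(gc3_bias * env$gc_count[cods]))
  }
  paste(out, collapse = "")
}

randomBackground <- function(n, gc = 0.4) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

randomVarRegion <- function(len) {
  paste(sample(JTT_ORDER, len, replace = TRUE, prob = JTT_FREQS),
        collapse = "")
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: number of species
#' and tree shape, ortholog-set counts, divergences (expected substitutions
#' per site), the domain-generating PSPM, decoy class counts, background
#' composition and architecture probabilities.
#'
#' @param seed RNG seed (mandatory; all randomness flows from it).
#' @param n_species number of species/assemblies.
#' @param tree_shape `"star"`, `"caterpillar"` or `"coalescent"`.
#' @param n_ortholog_sets one-to-one ortholog sets planted across all
#'   species.
#' @param families family label per species (default: species split into two
#'   families).
#' @param within_divergence divergence between gene-set ancestors within a
#'   genome (paralog diversity; subs/site).
#' @param species_divergence per-branch divergence along the species tree
#'   (ortholog diversity; subs/site).
#' @param pspm generating [PSPM-class] (default [defaultDomainPSPM()]).
#' @param p_threshold scan P-value every planted canonical domain must beat
#'   (and "group II" decoys must not).
#' @param decoy_p_floor "group II" decoy domains are rejection-sampled to
#'   scan P-values above this floor (diverged but motif-like).
#' @param decoys per-species decoy counts, named `groupII`, `no_nss`,
#'   `no_domain`.
#' @param multi_domain_p probability a gene carries a second domain.
#' @param p_no_cterm probability the stop codon immediately follows the final
#'   domain (no C-terminal extension).
#' @param bg_gc GC content of intergenic background.
#' @param bg_len mean intergenic spacer length (nt).
#' @param gc3_bias codon GC preference passed to [backTranslate()].
#' @param var_motif insert a conserved `CxxC` motif into ancestor variable
#'   regions.
#' @return validated configuration list of class `simConfig`.
#' @export
simConfig <- function(seed, n_species = 4, tree_shape = "caterpillar",
                      n_ortholog_sets = 5, families = NULL,
                      within_divergence = 0.5, species_divergence = 0.05,
                      pspm = NULL, p_threshold = 6e-11,
                      decoy_p_floor = 1e-8,
                      decoys = c(groupII = 1, no_nss = 1, no_domain = 1),
                      multi_domain_p = 0.2, p_no_cterm = 0.1,
                      bg_gc = 0.4, bg_len = 300, gc3_bias = 0,
                      var_motif = FALSE) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(families))
    families <- paste0("Fam", rep(c("A", "B"), length.out = n_species))
  stopifnot(length(families) == n_species, n_species >= 2,
            n_ortholog_sets >= 1, multi_domain_p >= 0, multi_domain_p <= 1,
            p_no_cterm >= 0, p_no_cterm <= 1, bg_gc > 0, bg_gc < 1,
            p_threshold > 0, p_threshold < 1,
            tree_shape %in% c("star", "caterpillar", "coalescent"))
  structure(list(seed = seed, n_species = n_species, tree_shape = tree_shape,
                 n_ortholog_sets = n_ortholog_sets, families = families,
                 within_divergence = within_divergence,
                 species_divergence = species_divergence, pspm = pspm,
                 p_threshold = p_threshold, decoy_p_floor = decoy_p_floor,
                 decoys = decoys, multi_domain_p = multi_domain_p,
                 p_no_cterm = p_no_cterm, bg_gc = bg_gc, bg_len = bg_len,
                 gc3_bias = gc3_bias, var_motif = var_motif),
            class = "simConfig")
}

simSpeciesTree <- function(config) {
  n <- config$n_species
  labels <- paste0("org", seq_len(n))
  if (n == 2L)
    return(ape::read.tree(text = paste0("(", labels[1], ",", labels[2], ");")))
  tr <- switch(config$tree_shape,
    star = ape::stree(n, type = "star", tip.label = labels),
    caterpillar = ape::stree(n, type = "left", tip.label = labels),
    coalescent = ape::rcoal(n, tip.label = labels))
  tr
}

## Evolve a list of segments (nss is held fixed; all other segments evolve
## under JTT) down the species tree with per-edge divergence t_edge.
## Returns a list of leaf-label -> segments.
evolveSegmentsAlongTree <- function(tree, segments, t_edge) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  node_seg <- vector("list", max(tree$edge))
  node_seg[[root]] <- segments
  ord <- order(tree$edge[, 1])  # parents before children for stree/rcoal
  evolveSeg <- function(seg, t) {
    seg$var <- evolveAASequence(seg$var, t)
    seg$domains <- vapply(seg$domains, evolveAASequence, character(1), t = t,
                          USE.NAMES = FALSE)
    seg$spacers <- vapply(seg$spacers, evolveAASequence, character(1), t = t,
                          USE.NAMES = FALSE)
    if (nzchar(seg$cterm)) seg$cterm <- evolveAASequence(seg$cterm, t)
    seg
  }
  ## walk edges so that each child is processed after its parent
  remaining <- seq_len(nrow(tree$edge))
  while (length(remaining)) {
    ready <- remaining[vapply(tree$edge[remaining, 1],
                              function(p) !is.null(node_seg[[p]]),
                              logical(1))]
    for (k in ready) {
      parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      node_seg[[child]] <- evolveSeg(node_seg[[parent]], t_edge)
    }
    remaining <- setdiff(remaining, ready)
  }
  out <- node_seg[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

assemblePrepro <- function(seg) {
  doms <- seg$domains
  body <- doms[1]
  if (length(doms) > 1L)
    for (i in 2:length(doms)) body <- paste0(body, seg$spacers[i - 1L], doms[i])
  paste0(seg$nss, seg$var, body, seg$cterm)
}

segArchitecture <- function(seg, width = 15L) {
  offs <- integer(length(seg$domains))
  pos <- nchar(seg$nss) + nchar(seg$var)
  for (i in seq_along(seg$domains)) {
    offs[i] <- pos
    pos <- pos + width + if (i <= length(seg$spacers)) nchar(seg$spacers[i]) else 0L
  }
  list(nss_len = nchar(seg$nss), var_len = nchar(seg$var),
       domain_offsets = offs,
       spacer_total = sum(nchar(seg$spacers)),
       cterm_len = nchar(seg$cterm))
}

## Leaf-level acceptance checks for a canonical locus: every domain beats the
## scan threshold, and start selection on the back-translated CDS picks the
## true start with the template's cleavage. Returns the cds or NULL.
checkCanonicalLocus <- function(seg, pspm, config, scorer, score_min) {
  for (d in seg$domains)
    if (scoreWindow(pspm, d) < score_min) return(NULL)
  prepro <- assemblePrepro(seg)
  cds <- backTranslate(prepro, config$gc3_bias)
  arch <- segArchitecture(seg)
  fs <- findStart(prepro, cds, arch$domain_offsets[1],
                  scorer, 0.400)
  if (isTRUE(fs$rejected) || fs$start != 0L || fs$nss_len != arch$nss_len)
    return(NULL)
  cds
}

## Generate the sequence-level canonical gene records for one family.
## Returns a data.frame of loci (one per species x ortholog set).
simulateFamilyGenes <- function(config, tree, organisms, family_label,
                                pspm, scorer, score_min, set_offset = 0L) {
  recs <- list()
  for (s in seq_len(config$n_ortholog_sets)) {
    repeat {
      nss <- nssTemplate()
      n_dom <- 1L + rbinom(1, 1, config$multi_domain_p)
      base <- list(
        nss = nss$aa,
        var = randomVarRegion(sample(25:60, 1)),
        domains = sampleFromPSPM(pspm, n_dom),
        spacers = if (n_dom > 1L) vapply(seq_len(n_dom - 1L), function(i)
          randomVarRegion(sample(3:10, 1)), character(1)) else character(0),
        cterm = if (runif(1) < config$p_no_cterm) "" else
          randomVarRegion(sample(2:8, 1)))
      if (config$var_motif && nchar(base$var) >= 6) {
        at <- sample(nchar(base$var) - 3L, 1)
        substr(base$var, at, at + 3L) <- paste0("C",
          substr(base$var, at + 1L, at + 2L), "C")
      }
      ## paralog diversity: the set ancestor diverges from the family base
      anc <- base
      anc$var <- evolveAASequence(anc$var, config$within_divergence)
      anc$domains <- vapply(anc$domains, evolveAASequence, character(1),
                            t = config$within_divergence, USE.NAMES = FALSE)
      if (nzchar(anc$cterm))
        anc$cterm <- evolveAASequence(anc$cterm, config$within_divergence)
      leaves <- evolveSegmentsAlongTree(tree, anc, config$species_divergence)
      leaves <- leaves[organisms]
      cds_list <- vector("list", length(organisms))
      ok <- TRUE
      for (li in seq_along(organisms)) {
        seg <- leaves[[li]]
        cds <- NULL
        for (try_ in seq_len(200)) {
          cds <- checkCanonicalLocus(seg, pspm, config, scorer, score_min)
          if (!is.null(cds)) break
          ## re-draw this leaf's drifted segments from the set ancestor at
          ## the per-branch divergence scale
          seg$var <- evolveAASequence(anc$var, config$species_divergence)
          seg$domains <- vapply(anc$domains, evolveAASequence,
                                character(1), t = config$species_divergence,
                                USE.NAMES = FALSE)
        }
        if (is.null(cds)) { ok <- FALSE; break }
        leaves[[li]] <- seg
        cds_list[[li]] <- cds
      }
      if (!ok) next
      for (li in seq_along(organisms)) {
        seg <- leaves[[li]]
        arch <- segArchitecture(seg)
        recs[[length(recs) + 1L]] <- data.frame(
          truth_id = sprintf("%s_set%d_%s", family_label, s + set_offset,
                             organisms[li]),
          organism = organisms[li], family = family_label,
          ortho_set = s + set_offset, class = "canonical",
          nss_len = arch$nss_len, var_len = arch$var_len,
          n_domains = length(seg$domains),
          domain_offsets = paste(arch$domain_offsets, collapse = ","),
          spacer_total = arch$spacer_total, cterm_len = arch$cterm_len,
          prepropeptide = assemblePrepro(seg), cds = cds_list[[li]],
          stringsAsFactors = FALSE)
      }
      break
    }
  }
  do.call(rbind, recs)
}

## Decoy loci for one species; same record shape, class labels the decoy.
simulateDecoys <- function(config, org, family_label, pspm, scorer,
                           score_min) {
  recs <- list()
  counts <- config$decoys
  nOf <- function(name) if (name %in% names(counts)) counts[[name]] else 0L
  addRec <- function(class_, prepro, cds, arch) {
    recs[[length(recs) + 1L]] <<- data.frame(
      truth_id = sprintf("%s_%s_%d", org, class_, length(recs) + 1L),
      organism = org, family = family_label, ortho_set = NA_integer_,
      class = class_, nss_len = arch$nss_len, var_len = arch$var_len,
      n_domains = arch$n_domains,
      domain_offsets = arch$domain_offsets,
      spacer_total = 0L, cterm_len = arch$cterm_len,
      prepropeptide = prepro, cds = cds, stringsAsFactors = FALSE)
  }
  pert <- perturbPSPM(pspm)
  for (i in seq_len(nOf("groupII"))) {
    ok <- FALSE
    for (try_ in seq_len(10000)) {
      dom <- sampleFromPSPM(pert, 1)
      pv <- scorePvalue(pspm, scoreWindow(pspm, dom))
      if (pv <= config$decoy_p_floor) next
      nss <- nssTemplate()
      var <- randomVarRegion(sample(8:20, 1))
      ct <- randomVarRegion(sample(2:6, 1))
      prepro <- paste0(nss$aa, var, dom, ct)
      ## no window of the whole decoy may reach the scan threshold (a
      ## diverged domain can partially re-align at a shifted offset)
      if (nrow(scanOrf(pspm, prepro, config$p_threshold)) == 0L) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("rejection sampling for groupII decoys failed; ",
           "loosen decoy_p_floor or change the generating matrix")
    addRec("groupII_decoy", prepro, backTranslate(prepro, config$gc3_bias),
           list(nss_len = nss$nss_len, var_len = nchar(var), n_domains = 1L,
                domain_offsets = as.character(nss$nss_len + nchar(var)),
                cterm_len = nchar(ct)))
  }
  for (i in seq_len(nOf("no_nss"))) {
    for (try_ in seq_len(10000)) {
      dom <- sampleFromPSPM(pspm, 1)
      if (scoreWindow(pspm, dom) < score_min) next
      var <- paste(sample(SAFE_NO_SIGNAL_AA, sample(12:25, 1),
                          replace = TRUE), collapse = "")
      prepro <- paste0("M", var, dom, randomVarRegion(sample(2:6, 1)))
      if (signalScore(scorer, prepro) <= 0.400) break
      if (try_ == 10000) stop("could not construct a signal-less decoy")
    }
    ct_len <- nchar(prepro) - 1L - nchar(var) - 15L
    addRec("no_nss_decoy", prepro, backTranslate(prepro, config$gc3_bias),
           list(nss_len = 0L, var_len = 1L + nchar(var), n_domains = 1L,
                domain_offsets = as.character(1L + nchar(var)),
                cterm_len = ct_len))
  }
  for (i in seq_len(nOf("no_domain"))) {
    for (try_ in seq_len(10000)) {
      nss <- nssTemplate()
      var <- randomVarRegion(sample(15:35, 1))
      prepro <- paste0(nss$aa, var)
      hits <- scanOrf(pspm, prepro, config$p_threshold)
      if (nrow(hits) == 0L) break
      if (try_ == 10000) stop("could not construct a domain-less decoy")
    }
    addRec("no_domain_decoy", prepro, backTranslate(prepro, config$gc3_bias),
           list(nss_len = nss$nss_len, var_len = nchar(var), n_domains = 0L,
                domain_offsets = "", cterm_len = 0L))
  }
  if (!length(recs)) return(NULL)
  do.call(rbind, recs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full dataset: assemblies, species tree and truth table
#'
#' Plants canonical gene loci (one per species per ortholog set, evolved
#' along the species tree under the JTT model) and the three decoy classes
#' into random intergenic background on both strands, one contig per species.
#' Every canonical locus's domains beat the scan threshold under the
#' generating matrix and every "group II" decoy stays below it (rejection
#' sampled); an in-frame stop codon immediately precedes each planted start
#' so the planted coordinates are exactly recoverable.
#'
#' @param config a [simConfig()].
#' @return list with `assemblies` (named list of [GenomeAssembly-class]),
#'   `tree` (`phylo`), `truth` (data.frame: one row per planted locus with
#'   contig, strand, 0-based half-open CDS span, class, family, ortholog-set
#'   id, segment lengths and sequences) and `pspm` (the generating matrix).
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  pspm <- config$pspm %||% defaultDomainPSPM()
  scorer <- heuristicSignalScorer()
  score_min <- scoreThreshold(pspm, config$p_threshold)
  tree <- simSpeciesTree(config)
  organisms <- tree$tip.label
  fam_of <- setNames(config$families, organisms)
  genes <- simulateFamilyGenes(config, tree, organisms, family_label = "sim",
                               pspm, scorer, score_min)
  genes$family <- unname(fam_of[genes$organism])
  loci <- genes
  for (org in organisms) {
    dec <- simulateDecoys(config, org, fam_of[[org]], pspm, scorer, score_min)
    if (!is.null(dec)) loci <- rbind(loci, dec)
  }
  assemblies <- list()
  truth <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (org in organisms) {
    sub <- loci[loci$organism == org, ]
    sub <- sub[sample.int(nrow(sub)), , drop = FALSE]
    parts <- character(0)
    offset <- 0L
    for (i in seq_len(nrow(sub))) {
      bg_n <- sample(seq(round(config$bg_len * 0.7),
                         round(config$bg_len * 1.3)), 1)
      bg <- randomBackground(bg_n, config$bg_gc)
      locus_nt <- paste0("TAA", sub$cds[i], sample(stops, 1))
      strand <- if (runif(1) < 0.5) "+" else "-"
      emit <- if (strand == "+") locus_nt else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(locus_nt)))
      parts <- c(parts, bg, emit)
      offset <- offset + nchar(bg)
      cds_len <- nchar(sub$cds[i])
      truth[[length(truth) + 1L]] <- cbind(
        sub[i, c("truth_id", "organism", "family", "ortho_set", "class",
                 "nss_len", "var_len", "n_domains", "domain_offsets",
                 "spacer_total", "cterm_len", "prepropeptide", "cds")],
        data.frame(contig = paste0(org, "_c1"), strand = strand,
                   cds_start = offset + 3L, cds_end = offset + 3L + cds_len,
                   stringsAsFactors = FALSE))
      offset <- offset + nchar(emit)
    }
    parts <- c(parts, randomBackground(sample(200:400, 1), config$bg_gc))
    contig <- paste(parts, collapse = "")
    sq <- Biostrings::DNAStringSet(setNames(contig, paste0(org, "_c1")))
    assemblies[[org]] <- GenomeAssembly(sq, assemblyId = org, organism = org,
                                        family = fam_of[[org]])
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(assemblies = assemblies, tree = tree, truth = truth, pspm = pspm)
}

#' Simulate a codon alignment with per-site selective regimes
#'
#' Star-tree codon evolution for exercising the sitewise dN/dS profiler:
#' every sequence descends independently from a common ancestor of sense
#' codons; each site receives a Poisson number of single-base mutation
#' events, synonymous changes are always accepted, non-synonymous changes
#' are accepted with probability `omegas[site]`, and mutations to stop
#' codons are rejected.
#'
#' @param n_seq number of sequences.
#' @param omegas per-site acceptance probability for non-synonymous changes
#'   (the simulated dN/dS regime).
#' @param events expected mutation events per codon site per sequence.
#' @param seed RNG seed.
#' @return character vector of `n_seq` in-frame codon sequences.
#' @export
simulateCodonAlignment <- function(n_seq, omegas, events = 2, seed = 1) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  anc <- sample(sense, length(omegas), replace = TRUE)
  evolveCodon <- function(cod, omega, nev) {
    for (e in seq_len(nev)) {
      v <- strsplit(cod, "")[[1]]
      p <- sample(3, 1)
      nuc <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      w <- v; w[p] <- nuc
      new <- paste(w, collapse = "")
      if (code[new] == "*") next
      if (code[new] == code[cod] || runif(1) < omega) cod <- new
    }
    cod
  }
  vapply(seq_len(n_seq), function(i)
    paste(mapply(function(cod, om) evolveCodon(cod, om, rpois(1, events)),
                 anc, omegas), collapse = ""), character(1))
}

#' Simulate two families with contrasting diversity
#'
#' Generates sequence-level gene tables for two labelled families whose
#' configurations differ (typically in `within_divergence`, for IOPD
#' contrasts, or `gc3_bias`, for GC contrasts). Each family comprises
#' `n_species` independent assemblies; within an assembly, a base gene is
#' generated and `n_ortholog_sets` paralogs are evolved from it at the
#' configured within-genome divergence, emulating diversification by gene
#' duplication. The result feeds directly into [computeIopds()],
#' [rankTukey()] and [logitTukey()].
#'
#' @param config_hi,config_lo [simConfig()]s for the two families
#'   (`n_species` assemblies with `n_ortholog_sets` genes each).
#' @return data.frame of gene records (`gene_id`, `assembly_id`, `organism`,
#'   `family`, architecture columns, `prepropeptide`, `cds`).
#' @export
simulateFamilyContrast <- function(config_hi, config_lo) {
  stopifnot(config_hi$n_species == config_lo$n_species)
  set.seed(config_hi$seed)
  out <- list()
  for (lab in c("hi", "lo")) {
    cf <- if (lab == "hi") config_hi else config_lo
    for (asm_i in seq_len(cf$n_species)) {
      asm <- sprintf("%s_asm%d", lab, asm_i)
      nss <- nssTemplate()
      n_dom <- 1L + rbinom(1, 1, cf$multi_domain_p)
      pspm <- cf$pspm %||% defaultDomainPSPM()
      base <- list(
        nss = nss$aa,
        var = randomVarRegion(sample(25:60, 1)),
        domains = sampleFromPSPM(pspm, n_dom),
        spacers = if (n_dom > 1L) vapply(seq_len(n_dom - 1L), function(i)
          randomVarRegion(sample(3:10, 1)), character(1)) else character(0),
        cterm = if (runif(1) < cf$p_no_cterm) "" else
          randomVarRegion(sample(2:8, 1)))
      for (g in seq_len(cf$n_ortholog_sets)) {
        seg <- base
        seg$var <- evolveAASequence(seg$var, cf$within_divergence)
        seg$domains <- vapply(seg$domains, evolveAASequence, character(1),
                              t = cf$within_divergence, USE.NAMES = FALSE)
        seg$spacers <- vapply(seg$spacers, evolveAASequence, character(1),
                              t = cf$within_divergence, USE.NAMES = FALSE)
        if (nzchar(seg$cterm))
          seg$cterm <- evolveAASequence(seg$cterm, cf$within_divergence)
        arch <- segArchitecture(seg)
        prepro <- assemblePrepro(seg)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = sprintf("%s_g%d", asm, g), assembly_id = asm,
          organism = asm, family = lab,
          nss_len = arch$nss_len, var_len = arch$var_len,
          n_domains = length(seg$domains),
          domain_offsets = paste(arch$domain_offsets, collapse = ","),
          spacer_total = arch$spacer_total, cterm_len = arch$cterm_len,
          prepropeptide = prepro, cds = backTranslate(prepro, cf$gc3_bias),
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, out)
  rownames(genes) <- NULL
  genes
}
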