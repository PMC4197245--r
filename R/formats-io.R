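## External representations: FASTA assemblies, MEME minimal motif format,
## rooted newick species trees, and TSV/CSV exports of supplementary gene and
## domain tables. All genomic coordinates written by this package are 0-based,
## half-open, with strand in {+,-}.

#' Read a genome assembly from FASTA
#'
#' Reads a multi-record nucleotide FASTA, normalizes lowercase to uppercase
#' and any non-`ACGT` IUPAC code to `N` (the number of normalized bases is
#' reported as a message), and returns a [GenomeAssembly-class].
#'
#' @param path FASTA file path.
#' @param assemblyId,organism,family metadata labels for the assembly.
#' @return a [GenomeAssembly-class]; record order is preserved.
#' @export
readGenomeFasta <- function(path, assemblyId = basename(path),
                            organism = assemblyId, family = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  sq <- Biostrings::readDNAStringSet(path)
  if (length(sq) == 0L) stop("empty FASTA file: ", path)
  ## drop description after first whitespace to get contig ids
  names(sq) <- sub("\\s.*$", "", names(sq))
  dup <- names(sq)[duplicated(names(sq))]
  if (length(dup))
    stop("duplicate contig id(s): ", paste(unique(dup), collapse = ", "))
  af <- Biostrings::alphabetFrequency(sq, collapse = TRUE)
  n_amb <- sum(af[setdiff(names(af), c("A", "C", "G", "T", "N"))])
  if (n_amb > 0) {
    sq <- Biostrings::replaceAmbiguities(sq, new = "N")
    message(n_amb, " ambiguous base(s) normalized to N")
  }
  GenomeAssembly(sq, assemblyId = assemblyId, organism = organism,
                 family = family)
}

#' Write a genome assembly to FASTA
#'
#' @param assembly a [GenomeAssembly-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(assembly, path) {
  Biostrings::writeXStringSet(contigs(assembly), path)
  invisible(path)
}

#' Read a motif from a MEME minimal motif format file
#'
#' Parses a MEME minimal motif format (version 4) file: the version line, the
#' protein alphabet, optional background letter frequencies and the first
#' `letter-probability matrix` block. When the background line is absent a
#' uniform background (1/20) is assumed with a warning.
#'
#' @param path path to a MEME minimal format file.
#' @return a [PSPM-class].
#' @export
readMemeMotif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  alpha_ln <- grep("^ALPHABET\\s*=", lines, value = TRUE)
  alphabet <- AA20
  if (length(alpha_ln)) {
    alphabet <- strsplit(gsub("^ALPHABET\\s*=\\s*", "", alpha_ln[1]), "")[[1]]
    if (!all(alphabet %in% AA20))
      stop("alphabet must be the 20-letter protein alphabet")
  }
  bg <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- character()
    i <- bg_at[1] + 1L
    while (i <= length(lines) && !grepl("^MOTIF", lines[i])) {
      toks <- c(toks, strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1L
    }
    toks <- toks[nzchar(toks)]
    if (length(toks) %% 2 != 0) stop("malformed background frequency line")
    letters_ <- toks[seq(1, length(toks), by = 2)]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    bg <- setNames(rep(NA_real_, 20), AA20)
    bg[letters_] <- vals
    if (anyNA(bg)) stop("background frequencies incomplete")
  } else {
    warning("no background line; assuming uniform background 1/20")
    bg <- setNames(rep(1 / 20, 20), AA20)
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stop("no MOTIF block found in ", path)
  motif_id <- strsplit(lines[motif_at[1]], "\\s+")[[1]][2]
  lp_at <- grep("^letter-probability matrix", lines)
  lp_at <- lp_at[lp_at > motif_at[1]][1]
  if (is.na(lp_at)) stop("no letter-probability matrix for motif ", motif_id)
  hdr <- lines[lp_at]
  getnum <- function(key, default = NA_real_) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9.eE+-]+)"), hdr))[[1]]
    if (length(m) < 2) default else as.numeric(m[2])
  }
  w <- getnum("w")
  alen <- getnum("alength", 20)
  nsites <- getnum("nsites", 0)
  if (!is.na(alen) && alen != length(alphabet))
    stop("alength does not match alphabet length")
  rows <- list()
  i <- lp_at + 1L
  while (i <= length(lines) && nzchar(lines[i]) &&
         grepl("^[-+0-9.eE[:space:]]+$", lines[i])) {
    rows[[length(rows) + 1L]] <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
    i <- i + 1L
  }
  if (!is.na(w) && length(rows) != w)
    stop("declared width ", w, " but found ", length(rows), " matrix rows")
  mat <- do.call(rbind, rows)
  if (ncol(mat) != length(alphabet))
    stop("matrix rows have ", ncol(mat), " entries, expected ", length(alphabet))
  bad <- which(abs(rowSums(mat) - 1) > 1e-4)
  if (length(bad))
    stop("probability row(s) not summing to 1: row ", paste(bad, collapse = ", "))
  probs <- matrix(0, nrow(mat), 20, dimnames = list(NULL, AA20))
  probs[, alphabet] <- mat
  probs <- probs / rowSums(probs)
  new("PSPM", motifId = motif_id, probs = probs, background = bg[AA20],
      pseudocount = 0, nsites = nsites)
}

#' Write a motif in MEME minimal motif format
#'
#' Emits a file that [readMemeMotif()] round-trips with per-entry error below
#' 1e-9 (probabilities are printed with 10 significant digits).
#'
#' @param pspm a [PSPM-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMemeMotif <- function(pspm, path) {
  stopifnot(is(pspm, "PSPM"))
  bg <- motifBackground(pspm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(AA20, collapse = "")), "",
               "Background letter frequencies",
               paste(AA20, formatC(bg, digits = 10, format = "g"),
                     collapse = " "), "",
               paste("MOTIF", motifId(pspm)),
               sprintf("letter-probability matrix: alength= 20 w= %d nsites= %s E= 0",
                       motifWidth(pspm), format(pspm@nsites))), con)
  p <- motifProbs(pspm)
  for (i in seq_len(nrow(p)))
    writeLines(paste(formatC(p[i, ], digits = 10, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' Read a rooted species tree from newick
#'
#' Reads a single rooted newick tree with unique leaf labels. Trees with a
#' basal trifurcation are rejected with instructions to root them first.
#'
#' @param path newick file path.
#' @return an [ape::read.tree] `phylo` object, validated.
#' @export
readSpeciesTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse a newick tree from ", path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, found several")
  validateSpeciesTree(tr)
  tr
}

validateSpeciesTree <- function(tr) {
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  root <- ape::Ntip(tr) + 1L
  n_children <- sum(tr$edge[, 1] == root)
  if (ape::Ntip(tr) > 2 && n_children > 2)
    stop("tree has a trifurcating (unrooted-style) root; ",
         "root it on a branch before use")
  invisible(tr)
}

#' Leaf depths of a species tree
#'
#' Depth of a leaf is the number of internal nodes on the path from the root
#' to that leaf, counting the root itself as an internal node. This is the
#' exponent used by the lineage-decay weighting stage: on a two-leaf tree both
#' leaves have depth 1, so a uniform decay factor cancels after normalization.
#'
#' @param tree a rooted `phylo` object.
#' @return named integer vector of depths, one per leaf label.
#' @export
leafDepths <- function(tree) {
  validateSpeciesTree(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  ## count edges walked from each tip up to the root
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depths <- vapply(seq_len(ntip), function(tip) {
    d <- 0L; node <- tip
    while (node != root) { node <- parent[node]; d <- d + 1L }
    d
  }, integer(1))
  setNames(depths, tree$tip.label)
}

#' Default column maps for supplementary-table exports
#'
#' The printed supplementary workbook layout is not standardized, so the
#' readers are header-map driven: each map entry names the column in the
#' export that carries the corresponding field.
#' @return named character vector mapping field -> column name.
#' @export
defaultGeneTableMap <- function() c(
  gene_id = "gene_id", organism = "organism", family = "family",
  sequence = "sequence", nss_len = "nss_len", var_len = "var_len",
  n_domains = "n_domains", spacer_total = "spacer_total",
  cterm_len = "cterm_len")

#' @rdname defaultGeneTableMap
#' @export
defaultDomainTableMap <- function() c(
  sequence = "sequence", bit_score = "bit_score", gene_ids = "gene_ids")

#' Read supplementary gene and domain tables
#'
#' Reads TSV/CSV exports of the survey's gene table (gene records with their
#' four-segment architecture) and domain table (15-mer domain sequences with
#' bit scores and associated genes). Records violating the type invariants
#' (segment lengths not tiling the sequence, domain sequences not of length
#' 15, empty gene associations) are rejected with their row numbers. Domain
#' rows referencing gene ids absent from the gene table produce a warning,
#' not an error.
#'
#' @param gene_path,domain_path paths to the two exports (TSV or CSV,
#'   auto-detected from the extension).
#' @param gene_map,domain_map header maps, see [defaultGeneTableMap()].
#' @return list with data.frames `genes` and `domains` (the `gene_ids` column
#'   is a list of character vectors) and integer `counts`.
#' @export
readSuppTables <- function(gene_path, domain_path,
                           gene_map = defaultGeneTableMap(),
                           domain_map = defaultDomainTableMap()) {
  readTab <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  }
  g_raw <- readTab(gene_path)
  missing_cols <- setdiff(gene_map, names(g_raw))
  if (length(missing_cols))
    stop("gene table lacks mapped column(s): ", paste(missing_cols, collapse = ", "))
  genes <- data.frame(
    gene_id = as.character(g_raw[[gene_map["gene_id"]]]),
    organism = as.character(g_raw[[gene_map["organism"]]]),
    family = as.character(g_raw[[gene_map["family"]]]),
    sequence = toupper(as.character(g_raw[[gene_map["sequence"]]])),
    nss_len = as.integer(g_raw[[gene_map["nss_len"]]]),
    var_len = as.integer(g_raw[[gene_map["var_len"]]]),
    n_domains = as.integer(g_raw[[gene_map["n_domains"]]]),
    spacer_total = as.integer(g_raw[[gene_map["spacer_total"]]]),
    cterm_len = as.integer(g_raw[[gene_map["cterm_len"]]]),
    stringsAsFactors = FALSE)
  tiled <- with(genes, nss_len + var_len + 15L * n_domains + spacer_total +
                  cterm_len) == nchar(genes$sequence)
  bad <- which(!tiled | genes$n_domains < 1L | genes$nss_len < 0L |
                 genes$var_len < 0L | genes$cterm_len < 0L)
  if (length(bad))
    stop("gene record(s) violating the segment-tiling invariant at row(s): ",
         paste(bad, collapse = ", "))
  d_raw <- readTab(domain_path)
  missing_cols <- setdiff(domain_map, names(d_raw))
  if (length(missing_cols))
    stop("domain table lacks mapped column(s): ", paste(missing_cols, collapse = ", "))
  domains <- data.frame(
    sequence = toupper(as.character(d_raw[[domain_map["sequence"]]])),
    bit_score = as.numeric(d_raw[[domain_map["bit_score"]]]),
    stringsAsFactors = FALSE)
  domains$gene_ids <- lapply(
    strsplit(as.character(d_raw[[domain_map["gene_ids"]]]), "[,;]\\s*"),
    function(x) x[nzchar(x)])
  bad <- which(nchar(domains$sequence) != 15L |
                 lengths(domains$gene_ids) == 0L)
  if (length(bad))
    stop("domain record(s) violating invariants (length-15 sequence, ",
         "non-empty gene set) at row(s): ", paste(bad, collapse = ", "))
  orphan <- setdiff(unlist(domains$gene_ids), genes$gene_id)
  if (length(orphan))
    warning("domain rows reference absent gene id(s): ",
            paste(orphan, collapse = ", "))
  list(genes = genes, domains = domains,
       counts = c(genes = nrow(genes), domains = nrow(domains)))
}
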