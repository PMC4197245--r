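# Shared fixtures, built in code at test time.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

# A toy PSPM with the given probability rows (list of named numeric vectors,
# filled to the full alphabet with zeros) and uniform background.
toyPSPM <- function(rows, pseudocount = 0, id = "toy") {
  probs <- matrix(0, length(rows), 20, dimnames = list(NULL, AA_LETTERS))
  for (i in seq_along(rows)) probs[i, names(rows[[i]])] <- rows[[i]]
  new("PSPM", motifId = id, probs = probs,
      background = setNames(rep(0.05, 20), AA_LETTERS),
      pseudocount = pseudocount, nsites = 1)
}

randomBg <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

randomAAString <- function(n, freqs = jttFrequencies()) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# Codon alignment generator, re-exported under the historical helper name.
simCodonAlignment <- function(n_seq, omegas, events = 2, seed = 1)
  simulateCodonAlignment(n_seq, omegas, events = events, seed = seed)

# Random weighted graph on n vertices for the clique-pruning oracle checks.
randomOrthoGraph <- function(n, p_edge = 0.35, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(n))
  prs <- combn(ids, 2)
  keep <- runif(ncol(prs)) < p_edge
  ed <- data.frame(from = prs[1, keep], to = prs[2, keep],
                   weight = round(runif(sum(keep), 1, 100), 1))
  igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = ids, organism = ids))
}

# Independent reference implementation of the ascending-score pruning rule:
# plain adjacency sets, explicit re-sort after every deletion.
prunedEdgesOracle <- function(graph) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  nodes <- igraph::V(graph)$name
  repeat {
    if (!nrow(ed)) break
    nb <- setNames(lapply(nodes, function(v)
      sort(c(ed$to[ed$from == v], ed$from[ed$to == v]))), nodes)
    lo <- pmin(ed$from, ed$to); hi <- pmax(ed$from, ed$to)
    ed <- ed[order(ed$weight, lo, hi), , drop = FALSE]
    victim <- NA
    for (k in seq_len(nrow(ed))) {
      a <- ed$from[k]; b <- ed$to[k]
      if (!setequal(setdiff(nb[[a]], b), setdiff(nb[[b]], a))) {
        victim <- k; break
      }
    }
    if (is.na(victim)) break
    ed <- ed[-victim, , drop = FALSE]
  }
  ed
}
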