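## Deterministic multi-species clustering-RBH orthology: local-alignment
## similarity scores, reciprocal-best-hit graph construction, and pruning of
## RBH edges in ascending score order until every connected component is a
## clique of genes sharing identical ortholog sets.

#' Cross-organism local-alignment similarity scores
#'
#' Smith-Waterman local alignment of every cross-organism pair of
#' prepropeptides, scored with the JTT-derived log-odds matrix (the same
#' matrix and gap penalties as [alignPair()]). The internal scorer is
#' symmetric; both directions are recorded to preserve the directional
#' best-hit contract, and externally computed tabular scores (query, subject,
#' bitscore) can be supplied to [buildRbhGraph()] in the same shape.
#'
#' @param seqs named character vector of amino-acid sequences (gene ids).
#' @param organisms character vector parallel to `seqs`.
#' @param gapOpening,gapExtension affine gap penalties.
#' @return data.frame with `query`, `subject`, `score` for all ordered
#'   cross-organism pairs; gene organisms attached as the `"organisms"`
#'   attribute (a named vector).
#' @export
similarityScores <- function(seqs, organisms, gapOpening = 11,
                             gapExtension = 1) {
  stopifnot(!is.null(names(seqs)), length(seqs) == length(organisms))
  if (length(unique(organisms)) < 2L)
    stop("need genes from at least two organisms")
  mat <- jttLogOddsMatrix()
  ids <- names(seqs)
  rows <- list()
  for (j in seq_along(seqs)) {
    other <- which(organisms != organisms[j] & seq_along(seqs) < j)
    if (!length(other)) next
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[other]), Biostrings::AAString(seqs[[j]]),
      substitutionMatrix = mat, gapOpening = gapOpening,
      gapExtension = gapExtension, type = "local", scoreOnly = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      query = c(ids[other], rep(ids[j], length(other))),
      subject = c(rep(ids[j], length(other)), ids[other]),
      score = c(sc, sc), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "organisms") <- setNames(organisms, ids)
  out
}

#' Build the reciprocal-best-hit graph
#'
#' An edge joins genes `a` and `b` (from different organisms) when `b` is
#' `a`'s unique best hit within `b`'s organism and vice versa. Ties for the
#' best hit produce no edge, keeping the construction deterministic. Edge
#' weight is the minimum of the two directional scores.
#'
#' @param scores data.frame with `query`, `subject`, `score` and an
#'   `"organisms"` attribute (named vector gene -> organism), as produced by
#'   [similarityScores()]; externally computed hit tables work if the
#'   attribute is supplied.
#' @param organisms optional named vector overriding the attribute.
#' @return an [igraph::graph_from_data_frame] undirected graph whose vertices
#'   carry an `organism` attribute and edges a `weight`.
#' @export
buildRbhGraph <- function(scores, organisms = attr(scores, "organisms")) {
  if (is.null(organisms)) stop("gene -> organism map required")
  genes <- names(organisms)
  bestHit <- function(q, target_org) {
    sub <- scores[scores$query == q &
                    organisms[scores$subject] == target_org, ]
    if (!nrow(sub)) return(NA_character_)
    top <- sub$score == max(sub$score)
    if (sum(top) != 1L) return(NA_character_)   # tie -> no best hit
    sub$subject[top]
  }
  edges <- list()
  orgs <- unique(organisms)
  for (q in genes) {
    for (o in setdiff(orgs, organisms[q])) {
      b <- bestHit(q, o)
      if (is.na(b) || q >= b) next   # handle each unordered pair once
      if (identical(bestHit(b, organisms[q]), q)) {
        w <- min(scores$score[scores$query == q & scores$subject == b],
                 scores$score[scores$query == b & scores$subject == q])
        edges[[length(edges) + 1L]] <- data.frame(
          from = q, to = b, weight = w, stringsAsFactors = FALSE)
      }
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), weight = numeric())
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = genes, organism = unname(organisms),
                          stringsAsFactors = FALSE))
  g
}

#' Prune an RBH graph to ortholog-set-consistent cliques
#'
#' Repeatedly scans the current edges in ascending weight order (ties broken
#' lexicographically on the gene-id pair); at the first edge whose endpoints
#' have unequal neighbor sets (excluding each other) the edge is deleted and
#' the scan restarts. At termination every edge's endpoints share identical
#' ortholog sets and every connected component is a clique. Components of at
#' least `min_group_size` members are emitted as orthologous groups, labelled
#' sequentially by descending size then lexicographic first member.
#'
#' @param graph an igraph from [buildRbhGraph()].
#' @param min_group_size minimum members per emitted group (default 4).
#' @return data.frame with `group_id`, `gene_id`, `organism`.
#' @export
pruneToCliques <- function(graph, min_group_size = 4) {
  g <- graph
  repeat {
    ed <- igraph::as_data_frame(g, what = "edges")
    if (!nrow(ed)) break
    lo <- pmin(ed$from, ed$to); hi <- pmax(ed$from, ed$to)
    ord <- order(ed$weight, lo, hi)
    deleted <- FALSE
    for (k in ord) {
      a <- ed$from[k]; b <- ed$to[k]
      na_ <- setdiff(names(igraph::neighbors(g, a)), b)
      nb_ <- setdiff(names(igraph::neighbors(g, b)), a)
      if (!setequal(na_, nb_)) {
        g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
        deleted <- TRUE
        break
      }
    }
    if (!deleted) break
  }
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  member <- Filter(function(m) length(m) >= min_group_size, member)
  if (!length(member))
    return(data.frame(group_id = integer(), gene_id = character(),
                      organism = character()))
  member <- lapply(member, sort)
  ord <- order(-lengths(member), vapply(member, `[`, character(1), 1))
  member <- member[ord]
  orgv <- setNames(igraph::V(g)$organism, igraph::V(g)$name)
  do.call(rbind, lapply(seq_along(member), function(i)
    data.frame(group_id = i, gene_id = member[[i]],
               organism = unname(orgv[member[[i]]]),
               stringsAsFactors = FALSE)))
}
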