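# Molecular similarity networks: nodes are molecules, edges carry pairwise
# Tanimoto similarity at or above a cutoff.  The same machinery accepts any
# precomputed similarity matrix (e.g. sequence identities), covering
# similarity-network topology construction generally.

#' Build a molecular similarity network
#'
#' Pairwise Tanimoto similarity on circular (Morgan-style) fingerprints;
#' an undirected edge is kept iff similarity >= cutoff.  Self-pairs are
#' excluded by construction; isolated nodes are kept.
#'
#' @param mols list of [MoleculeRecord] or character vector of SMILES
#' @param cutoff similarity threshold in \[0, 1\] (e.g. 0.5 for a 50%
#'   similarity network)
#' @return a `SimilarityNetwork`: list(graph = igraph, cutoff)
#' @export
build_similarity_network <- function(mols, cutoff = 0.5) {
  if (is.character(mols)) mols <- lapply(mols, sanitize_molecule)
  stopifnot(length(mols) >= 2L, cutoff >= 0, cutoff <= 1)
  ids <- vapply(mols, function(m)
    if (is.na(m$identifier)) m$structure else m$identifier, character(1))
  if (anyDuplicated(ids)) stop("duplicate node identifiers: ",
                               paste(ids[duplicated(ids)], collapse = ","))
  fps <- lapply(mols, fingerprint, kind = "circular")
  n <- length(mols)
  sim <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- suppressWarnings(tanimoto(fps[[i]], fps[[j]]))
    sim[i, j] <- sim[j, i] <- s
  }
  build_from_matrix(ids, sim, cutoff)
}

#' Build a similarity network from a precomputed matrix
#'
#' @param ids node identifiers (unique)
#' @param matrix square symmetric similarity matrix with unit diagonal
#' @param cutoff edge threshold; the diagonal is ignored
#' @return a `SimilarityNetwork`
#' @export
build_from_matrix <- function(ids, matrix, cutoff = 0.5) {
  n <- length(ids)
  stopifnot(is.matrix(matrix), nrow(matrix) == n, ncol(matrix) == n)
  if (anyDuplicated(ids)) stop("duplicate node identifiers")
  if (max(abs(matrix - t(matrix))) > 1e-9) stop("similarity matrix is asymmetric")
  if (max(abs(diag(matrix) - 1)) > 1e-9) stop("similarity matrix diagonal must be 1")
  edges <- which(upper.tri(matrix) & matrix >= cutoff, arr.ind = TRUE)
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = ids)
  if (nrow(edges)) {
    gr <- igraph::add_edges(gr, t(edges))
    gr <- igraph::set_edge_attr(gr, "weight",
                                value = matrix[edges])
  }
  structure(list(graph = gr, cutoff = cutoff), class = "SimilarityNetwork")
}

#' @export
print.SimilarityNetwork <- function(x, ...) {
  cat("<SimilarityNetwork>", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges (cutoff", x$cutoff, ")\n")
  invisible(x)
}

#' Export a similarity network
#'
#' GraphML (lossless, re-importable) or SIF with a companion
#' `<path>.edges.tsv` holding the edge weights; isolated nodes get their
#' own SIF line.
#'
#' @param net a `SimilarityNetwork`
#' @param path output file
#' @param format `"graphml"` or `"sif"`
#' @return invisibly `path`
#' @export
export_graph <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  gr <- net$graph
  if (format == "graphml") {
    igraph::write_graph(gr, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(gr)
    w <- igraph::edge_attr(gr, "weight")
    lines <- if (nrow(el)) paste(el[, 1], "sim", el[, 2]) else character(0)
    isolated <- setdiff(igraph::V(gr)$name, unique(c(el)))
    writeLines(c(lines, isolated), path)
    utils::write.table(
      data.frame(source = el[, 1], interaction = rep("sim", nrow(el)),
                 target = el[, 2], weight = if (nrow(el)) w else numeric(0)),
      paste0(path, ".edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a GraphML similarity network
#' @param path GraphML file written by [export_graph()]
#' @param cutoff cutoff to record on the object
#' @return a `SimilarityNetwork`
#' @export
import_graphml <- function(path, cutoff = NA_real_) {
  gr <- igraph::read_graph(path, format = "graphml")
  structure(list(graph = gr, cutoff = cutoff), class = "SimilarityNetwork")
}
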