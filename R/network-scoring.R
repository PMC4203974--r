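# Gene-network topology as a per-variant continuous feature: the scaled
# centrality (empirical CDF position) of the variant's associated gene,
# maximized over genes and networks.

#' Build a gene network with precomputed centrality percentiles
#'
#' Self-loops and duplicate edges are removed on load. Centralities are
#' computed for every node and converted to empirical-CDF percentiles with
#' the `<=` convention: the percentile of a gene is the fraction of genes
#' whose centrality is less than or equal to its own (so the minimum gene
#' gets `1/N`, the maximum 1, and ties share a value).
#'
#' @param edges a two-column `data.frame` of gene ids (an edge list), or a
#'   path to a TSV with two columns.
#' @param name network label.
#' @param centrality `"degree"` (default), `"betweenness"`, or
#'   `"closeness"`.
#' @param directed treat the edge list as directed.
#' @return an object of class `"gene_network"`.
#' @export
build_network <- function(edges, name = "network",
                          centrality = c("degree", "betweenness", "closeness"),
                          directed = FALSE) {
  centrality <- match.arg(centrality)
  if (is.character(edges) && length(edges) == 1) {
    edges <- utils::read.table(edges, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = directed)
  g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
  cent <- switch(centrality,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g),
    closeness = suppressWarnings(igraph::closeness(g))
  )
  cent[is.na(cent)] <- 0
  perc <- stats::ecdf(cent)(cent) # (# genes with centrality <= own) / N
  names(perc) <- names(cent)
  structure(
    list(
      name = name, graph = g, centrality_kind = centrality,
      centrality = cent, percentile = perc
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(
    "Gene network '", x$name, "': ", igraph::vcount(x$graph), " genes, ",
    igraph::ecount(x$graph), " edges; centrality: ", x$centrality_kind, "\n",
    sep = ""
  )
  invisible(x)
}

#' Centrality percentile of a gene in a network
#'
#' @param network a [build_network()] object.
#' @param gene gene id.
#' @return empirical CDF value in `(0, 1]`, or `NA` when the gene is not in
#'   the network.
#' @export
centrality_percentile <- function(network, gene) {
  out <- unname(network$percentile[gene])
  out
}

#' Network score of a variant's associated genes
#'
#' The maximum centrality percentile over all (gene, network) pairs; `NA`
#' when no associated gene is present in any network.
#'
#' @param associated_genes character vector of gene ids.
#' @param networks list of [build_network()] objects.
#' @return value in `(0, 1]` or `NA`.
#' @export
variant_network_score <- function(associated_genes, networks) {
  if (length(associated_genes) == 0 || length(networks) == 0) return(NA_real_)
  vals <- unlist(lapply(networks, centrality_percentile, gene = associated_genes))
  if (all(is.na(vals))) return(NA_real_)
  max(vals, na.rm = TRUE)
}
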