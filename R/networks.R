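#' Construct a gene co-expression network
#'
#' Undirected graph with genes as nodes and significant pairwise Pearson
#' correlations as edges. Isolated nodes are retained so node counts reflect
#' the full post-filtering gene list.
#'
#' @param nodes Character vector of gene ids (includes isolated genes).
#' @param edges data.frame with columns `gene_a`, `gene_b`, `r`, `p_raw`,
#'   `q_fdr`; each unordered pair at most once.
#' @return A `gene_network` object.
#' @export
gene_network <- function(nodes, edges) {
  edges <- as.data.frame(edges)
  need <- c("gene_a", "gene_b", "r", "p_raw", "q_fdr")
  if (!all(need %in% names(edges)))
    stop("gene network edges need columns: ", paste(need, collapse = ", "))
  edges <- canonicalize_edges(edges, "gene_a", "gene_b")
  check_edge_sanity(edges, "gene_a", "gene_b", nodes)
  if (any(edges$r < -1 | edges$r > 1)) stop("correlation outside [-1, 1]")
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "gene_network")
}

#' Construct a pathway co-expression network
#'
#' Pathways as nodes; an edge's weight is the mean Pearson correlation of the
#' gene edges crossing the two pathways' member sets, `n_gene_edges` the
#' number of contributing gene edges, `p_perm` the permutation p-value (NA
#' until [edge_significance()] is applied).
#'
#' @param nodes Character vector of pathway ids (includes isolated pathways).
#' @param edges data.frame with columns `pathway_a`, `pathway_b`, `weight`,
#'   `n_gene_edges`, and optionally `p_perm`.
#' @return A `pathway_network` object.
#' @export
pathway_network <- function(nodes, edges) {
  edges <- as.data.frame(edges)
  need <- c("pathway_a", "pathway_b", "weight", "n_gene_edges")
  if (!all(need %in% names(edges)))
    stop("pathway network edges need columns: ", paste(need, collapse = ", "))
  if (is.null(edges$p_perm)) edges$p_perm <- rep(NA_real_, nrow(edges))
  edges <- canonicalize_edges(edges, "pathway_a", "pathway_b")
  check_edge_sanity(edges, "pathway_a", "pathway_b", nodes)
  if (nrow(edges) && any(edges$weight < -1 | edges$weight > 1))
    stop("pathway edge weight outside [-1, 1]")
  if (nrow(edges) && any(edges$n_gene_edges < 1))
    stop("pathway edge with no contributing gene edges")
  structure(list(nodes = as.character(nodes), edges = edges),
            class = "pathway_network")
}

# store each unordered pair once, node_a < node_b, rows sorted for
# deterministic output
canonicalize_edges <- function(edges, a, b) {
  if (!nrow(edges)) {
    edges[[a]] <- character(0); edges[[b]] <- character(0)
    return(edges)
  }
  na <- as.character(edges[[a]]); nb <- as.character(edges[[b]])
  edges[[a]] <- pmin(na, nb)
  edges[[b]] <- pmax(na, nb)
  edges <- edges[order(edges[[a]], edges[[b]]), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

check_edge_sanity <- function(edges, a, b, nodes) {
  if (anyDuplicated(nodes)) stop("duplicate node id")
  if (!nrow(edges)) return(invisible(edges))
  if (any(edges[[a]] == edges[[b]])) stop("self-loop edge not allowed")
  key <- paste(edges[[a]], edges[[b]], sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edge pair")
  missing <- setdiff(c(edges[[a]], edges[[b]]), nodes)
  if (length(missing)) stop("edge references unknown node '", missing[1L], "'")
  invisible(edges)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene co-expression network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
print.pathway_network <- function(x, ...) {
  n_sig <- if (all(is.na(x$edges$p_perm))) "unassessed" else
    sum(x$edges$p_perm < 0.05, na.rm = TRUE)
  cat("Pathway co-expression network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (p_perm < 0.05:", n_sig, ")\n")
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param network A `gene_network` or `pathway_network`.
#' @return An undirected igraph graph carrying the edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, c("gene_network", "pathway_network")))
  ab <- if (inherits(network, "gene_network")) c("gene_a", "gene_b") else
    c("pathway_a", "pathway_b")
  el <- network$edges
  df <- cbind(data.frame(from = el[[ab[1L]]], to = el[[ab[2L]]]),
              el[, setdiff(names(el), ab), drop = FALSE])
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

network_node_columns <- function(network) {
  if (inherits(network, "gene_network")) c("gene_a", "gene_b")
  else c("pathway_a", "pathway_b")
}
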