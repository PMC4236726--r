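#' Connectivity impact of deleting a pathway set
#'
#' Models a drug (or other intervention) as simultaneous deletion of its
#' targeted pathways from the pathway network. Fractions use the original
#' network's node and edge counts as denominators; first neighbors exclude
#' the targets themselves.
#'
#' @param pcn A `pathway_network`.
#' @param targets Non-empty character vector of target pathway ids; targets
#'   absent from the network are reported via message and ignored (error if
#'   none remain).
#' @param hub_k Number of post-deletion hubs to report (default 10).
#' @return List with `target_set`, `first_neighbors`,
#'   `first_neighbor_fraction`, `incident_edge_fraction`,
#'   `nodes_after_deletion`, `isolated_after_deletion`, `new_hubs`,
#'   `circle_fraction` (fraction of 3-node circles containing >= 1 target).
#' @export
remove_pathways <- function(pcn, targets, hub_k = 10L) {
  stopifnot(inherits(pcn, "pathway_network"))
  if (!length(targets)) stop("target set must be non-empty")
  targets <- unique(as.character(targets))
  unknown <- setdiff(targets, pcn$nodes)
  if (length(unknown) == length(targets))
    stop("no target pathway present in the network")
  if (length(unknown))
    message("ignoring ", length(unknown), " target(s) absent from the network: ",
            paste(unknown, collapse = ", "))
  targets <- setdiff(targets, unknown)
  e <- pcn$edges
  n_nodes <- length(pcn$nodes)
  n_edges <- nrow(e)
  touches <- e$pathway_a %in% targets | e$pathway_b %in% targets
  fn <- setdiff(unique(c(e$pathway_b[e$pathway_a %in% targets],
                         e$pathway_a[e$pathway_b %in% targets])), targets)
  keep_nodes <- setdiff(pcn$nodes, targets)
  after <- pathway_network(keep_nodes, e[!touches, , drop = FALSE])
  deg_after <- igraph::degree(as_igraph(after))
  tri <- enumerate_circles(pcn, 3L)$circles
  circ_frac <- if (nrow(tri))
    mean(apply(tri, 1L, function(r) any(r %in% targets))) else 0
  list(target_set = sort(targets),
       first_neighbors = sort(fn),
       first_neighbor_fraction = length(fn) / n_nodes,
       incident_edge_fraction = if (n_edges) sum(touches) / n_edges else 0,
       nodes_after_deletion = length(keep_nodes),
       isolated_after_deletion = sort(names(deg_after)[deg_after == 0]),
       new_hubs = top_hubs(after, hub_k),
       circle_fraction = circ_frac)
}

#' Compare the network impact of several named target sets
#'
#' One [remove_pathways()] row per named set, all sharing the original
#' network's denominators, sorted by `circle_fraction` descending.
#'
#' @param pcn A `pathway_network`.
#' @param named_sets Named list (>= 2 entries) of pathway id vectors, e.g.
#'   drugs, top hubs, category selections.
#' @param hub_k Number of post-deletion hubs per row (default 10).
#' @return data.frame with one row per set: `name`, `n_targets`,
#'   `first_neighbor_fraction`, `incident_edge_fraction`,
#'   `nodes_after_deletion`, `n_isolated_after`, `circle_fraction`,
#'   `new_hubs` (semicolon-joined).
#' @export
compare_target_sets <- function(pcn, named_sets, hub_k = 10L) {
  if (length(named_sets) < 2L || is.null(names(named_sets)))
    stop("need at least two named target sets")
  rows <- lapply(names(named_sets), function(nm) {
    rep <- remove_pathways(pcn, named_sets[[nm]], hub_k = hub_k)
    data.frame(name = nm,
               n_targets = length(rep$target_set),
               first_neighbor_fraction = rep$first_neighbor_fraction,
               incident_edge_fraction = rep$incident_edge_fraction,
               nodes_after_deletion = rep$nodes_after_deletion,
               n_isolated_after = length(rep$isolated_after_deletion),
               circle_fraction = rep$circle_fraction,
               new_hubs = paste(rep$new_hubs, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$circle_fraction, out$name), ]
  rownames(out) <- NULL
  out
}

#' Highest-degree pathways of one category
#'
#' @param pcn A `pathway_network`.
#' @param annotation A `pathway_annotation` providing categories.
#' @param category Category label to select from.
#' @param k Number of pathways; if more than available, all are returned
#'   with a warning. Ties broken lexicographically as in [top_hubs()].
#' @return Character vector of pathway ids, ordered by degree.
#' @export
select_category_set <- function(pcn, annotation, category, k) {
  stopifnot(inherits(pcn, "pathway_network"),
            inherits(annotation, "pathway_annotation"))
  categ <- annotation$pathway_category
  members <- intersect(pcn$nodes, names(categ)[categ == category])
  if (!length(members))
    stop("no pathway of category '", category, "' in the network")
  deg <- igraph::degree(as_igraph(pcn))[members]
  ord <- order(-deg, members)
  if (k > length(members)) {
    warning("only ", length(members), " pathway(s) of category '", category,
            "' available (k = ", k, ")")
    k <- length(members)
  }
  members[ord][seq_len(k)]
}

#' Expected vs observed pathway connectivity
#'
#' Asks whether pathway hubs are merely the pathways of gene hubs and/or the
#' largest pathways. Each pathway's expected score is the rank-average of
#' (sum of member-gene degrees in the gene network, member-gene count in the
#' gene network); `discrepancy = expected_rank - observed_rank` (ranks 1 =
#' most connected), so positive means less connected than expected and
#' negative more connected than expected.
#'
#' @param gcn The `gene_network` of the same run.
#' @param pcn The `pathway_network` of the same run.
#' @param annotation A `pathway_annotation`.
#' @return data.frame per pathway: `pathway`, `observed_degree`,
#'   `observed_rank`, `expected_rank`, `discrepancy`. Pathways with no
#'   member gene in the gene network are excluded with a warning.
#' @export
hub_expectation <- function(gcn, pcn, annotation) {
  stopifnot(inherits(gcn, "gene_network"), inherits(pcn, "pathway_network"),
            inherits(annotation, "pathway_annotation"))
  gdeg <- igraph::degree(as_igraph(gcn))
  pdeg <- igraph::degree(as_igraph(pcn))
  pws <- pcn$nodes
  members <- lapply(annotation$pathway_genes[pws],
                    function(g) intersect(g, gcn$nodes))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("excluding ", sum(empty),
            " pathway(s) with no member gene in the gene network: ",
            paste(pws[empty], collapse = ", "))
    pws <- pws[!empty]; members <- members[!empty]
  }
  if (!length(pws)) stop("no pathway with gene-network members")
  deg_sum <- vapply(members, function(g) sum(gdeg[g]), numeric(1L))
  n_genes <- lengths(members)
  expected_score <- (rank(-deg_sum, ties.method = "average") +
                     rank(-n_genes, ties.method = "average")) / 2
  expected_rank <- rank(expected_score, ties.method = "average")
  observed_rank <- rank(-pdeg[pws], ties.method = "average")
  out <- data.frame(pathway = pws,
                    observed_degree = unname(pdeg[pws]),
                    observed_rank = unname(observed_rank),
                    expected_rank = unname(expected_rank),
                    discrepancy = unname(expected_rank - observed_rank))
  out <- out[order(out$discrepancy, out$pathway), ]
  rownames(out) <- NULL
  out
}
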