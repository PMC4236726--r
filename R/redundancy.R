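#' Effect of deleting one gene on a pathway's crosstalk
#'
#' Removes the gene and its incident gene edges from the gene network,
#' re-aggregates the pathway network, and contrasts the focal pathway's
#' crosstalk before vs after. With `recompute_p = TRUE` the null weights are
#' recomputed on the reduced gene set reusing the stored permutation label
#' assignments, so before/after p-values are directly comparable (fresh
#' permutations would confound the deletion effect with Monte-Carlo noise).
#'
#' @param gcn A `gene_network` containing `gene`.
#' @param annotation A `pathway_annotation` containing `focal_pathway`.
#' @param null A `null_ensemble` (with pooled data if `recompute_p`).
#' @param gene Gene id to delete.
#' @param focal_pathway Pathway whose crosstalk is reported.
#' @param alpha_pcn Significance level for pathway edges (default 0.05).
#' @param recompute_p Recompute null weights on the reduced gene set
#'   (default TRUE). If FALSE the original null weights are reused as-is.
#' @return List with `gene`, `focal_pathway`, `degree_before`,
#'   `degree_after` (significant crosstalk partners of the focal pathway)
#'   and `changed_edges`, a data.frame of focal-pathway edges with
#'   weight/p before and after.
#' @export
gene_deletion_impact <- function(gcn, annotation, null, gene, focal_pathway,
                                 alpha_pcn = 0.05, recompute_p = TRUE) {
  stopifnot(inherits(gcn, "gene_network"),
            inherits(annotation, "pathway_annotation"),
            inherits(null, "null_ensemble"))
  if (!gene %in% gcn$nodes) stop("unknown gene '", gene, "'")
  if (!focal_pathway %in% names(annotation$pathway_genes))
    stop("unknown pathway '", focal_pathway, "'")
  before_pcn <- edge_significance(aggregate_pathway_edges(gcn, annotation),
                                  null, alpha_pcn)
  reduced <- delete_gene(gcn, gene)
  null_after <- if (recompute_p) recompute_null_weights(null, reduced$nodes)
                else null
  after_pcn <- edge_significance(aggregate_pathway_edges(reduced, annotation),
                                 null_after, alpha_pcn)
  focal_edges <- function(pcn) {
    e <- pcn$edges
    e[e$pathway_a == focal_pathway | e$pathway_b == focal_pathway, ,
      drop = FALSE]
  }
  eb <- focal_edges(before_pcn)
  ea <- focal_edges(after_pcn)
  kb <- pair_key(eb$pathway_a, eb$pathway_b)
  ka <- pair_key(ea$pathway_a, ea$pathway_b)
  keys <- sort(union(kb, ka))
  parts <- strsplit(keys, "|", fixed = TRUE)
  changed <- data.frame(
    pathway_a = vapply(parts, `[[`, character(1L), 1L),
    pathway_b = vapply(parts, `[[`, character(1L), 2L),
    weight_before = eb$weight[match(keys, kb)],
    weight_after = ea$weight[match(keys, ka)],
    p_before = eb$p_perm[match(keys, kb)],
    p_after = ea$p_perm[match(keys, ka)])
  list(gene = gene, focal_pathway = focal_pathway,
       degree_before = nrow(eb), degree_after = nrow(ea),
       changed_edges = changed,
       pcn_before = before_pcn, pcn_after = after_pcn)
}

#' Third vertices of all 3-node circles through a pathway edge
#'
#' Every pathway adjacent to both endpoints of an existing edge is the third
#' vertex of one triangle through it; these are the redundant crosstalk
#' paths of that edge.
#'
#' @param pcn A `pathway_network`.
#' @param pathway_a,pathway_b Endpoints of an existing edge.
#' @return Sorted character vector of shared-neighbor pathways.
#' @export
circles_on_edge <- function(pcn, pathway_a, pathway_b) {
  stopifnot(inherits(pcn, "pathway_network"))
  e <- pcn$edges
  keys <- pair_key(e$pathway_a, e$pathway_b)
  if (!pair_key(pathway_a, pathway_b) %in% keys)
    stop("no edge between '", pathway_a, "' and '", pathway_b, "'")
  nbr <- function(v) {
    c(e$pathway_b[e$pathway_a == v], e$pathway_a[e$pathway_b == v])
  }
  sort(setdiff(intersect(nbr(pathway_a), nbr(pathway_b)),
               c(pathway_a, pathway_b)))
}

#' Group 3-node pathway circles by category multiset
#'
#' Each triangle is reduced to the sorted multiset of its three members'
#' pathway categories (`"uncategorized"` is a legal label); circles are
#' grouped by multiset with counts, sorted by count descending, ties broken
#' lexicographically on the multiset.
#'
#' @param circles Length-3 circle set from [enumerate_circles()].
#' @param annotation A `pathway_annotation` providing categories.
#' @return data.frame with `category_1..3`, `count`, and `members` (list
#'   column of the underlying pathway circles).
#' @export
categorize_circles <- function(circles, annotation) {
  stopifnot(inherits(annotation, "pathway_annotation"))
  if (!identical(circles$length, 3L)) stop("expects length-3 circles")
  m <- circles$circles
  if (!nrow(m)) {
    return(data.frame(category_1 = character(0), category_2 = character(0),
                      category_3 = character(0), count = integer(0)))
  }
  categ <- annotation$pathway_category
  cat_of <- function(p) {
    out <- unname(categ[p])
    out[is.na(out)] <- "uncategorized"
    out
  }
  trip <- t(apply(m, 1L, function(r) sort(cat_of(r))))
  key <- apply(trip, 1L, paste, collapse = "\r")
  grp <- split(seq_len(nrow(m)), key)
  out <- data.frame(
    category_1 = vapply(strsplit(names(grp), "\r"), `[[`, character(1L), 1L),
    category_2 = vapply(strsplit(names(grp), "\r"), `[[`, character(1L), 2L),
    category_3 = vapply(strsplit(names(grp), "\r"), `[[`, character(1L), 3L),
    count = lengths(grp))
  out$members <- lapply(grp, function(i) m[i, , drop = FALSE])
  out <- out[order(-out$count, out$category_1, out$category_2, out$category_3), ]
  rownames(out) <- NULL
  out
}

#' Export category circles as (category1, category2, category3, count) rows
#' @param category_circles data.frame from [categorize_circles()].
#' @param path Output path.
#' @export
write_category_circles <- function(category_circles, path) {
  utils::write.table(
    category_circles[, c("category_1", "category_2", "category_3", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
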