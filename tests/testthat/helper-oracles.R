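# Independent brute-force oracles and toy builders used across the suite.
# Oracles deliberately share no code with the package implementation.

# Erdos-Renyi style random undirected graph as a symmetric adjacency matrix
random_adjacency <- function(n, p_edge, node_prefix = "n") {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p_edge)
  a <- a + t(a)
  dimnames(a) <- list(paste0(node_prefix, sprintf("%02d", seq_len(n))),
                      paste0(node_prefix, sprintf("%02d", seq_len(n))))
  a
}

adjacency_to_pathway_network <- function(a) {
  idx <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  pathway_network(rownames(a), data.frame(
    pathway_a = rownames(a)[idx[, 1L]],
    pathway_b = rownames(a)[idx[, 2L]],
    weight = rep(0.5, nrow(idx)),
    n_gene_edges = rep(1L, nrow(idx))))
}

# exhaustive subset/ordering enumeration of simple cycles of length 3 or 4,
# returned as sorted canonical node-sequence keys
oracle_cycles <- function(a, len) {
  nodes <- rownames(a)
  n <- length(nodes)
  if (n < len) return(character(0))
  found <- character(0)
  for (subset in utils::combn(seq_len(n), len, simplify = FALSE)) {
    perms <- all_permutations(subset)
    for (ord in perms) {
      ok <- TRUE
      for (i in seq_len(len)) {
        j <- if (i == len) 1L else i + 1L
        if (a[ord[i], ord[j]] != 1L) { ok <- FALSE; break }
      }
      if (ok) {
        # canonical key: lexicographically smallest rotation/reflection
        seqs <- character(0)
        lab <- nodes[ord]
        for (d in list(lab, rev(lab)))
          for (s in seq_len(len))
            seqs <- c(seqs, paste(d[((seq_len(len) + s - 2L) %% len) + 1L],
                                  collapse = "|"))
        found <- c(found, min(seqs))
      }
    }
  }
  sort(unique(found))
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

circles_to_keys <- function(circles) {
  m <- circles$circles
  if (!nrow(m)) return(character(0))
  sort(apply(m, 1L, paste, collapse = "|"))
}

# brute-force suffix-min BH oracle: q_(i) = min over j >= i of p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  q <- numeric(m)
  for (i in seq_len(m))
    q[ord[i]] <- min(1, scaled[i:m])
  q
}

# brute-force pathway aggregation: loop over every gene edge and every
# unordered pathway pair, checking cross-membership directly
oracle_aggregate <- function(gcn, annotation) {
  pg <- annotation$pathway_genes
  pws <- names(pg)
  acc <- list()
  e <- gcn$edges
  for (i in seq_len(nrow(e))) {
    seen <- character(0)
    for (ia in seq_along(pws)) for (ib in seq_along(pws)) {
      if (ia == ib) next
      P <- pws[ia]; Q <- pws[ib]
      cross <- (e$gene_a[i] %in% pg[[P]] && e$gene_b[i] %in% pg[[Q]]) ||
               (e$gene_b[i] %in% pg[[P]] && e$gene_a[i] %in% pg[[Q]])
      if (!cross) next
      key <- paste(min(P, Q), max(P, Q), sep = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      acc[[key]] <- c(acc[[key]], e$r[i])
    }
  }
  if (!length(acc))
    return(data.frame(pair = character(0), weight = numeric(0),
                      n = integer(0)))
  data.frame(pair = names(acc),
             weight = vapply(acc, mean, numeric(1L)),
             n = lengths(acc), row.names = NULL)[order(names(acc)), ]
}

# small gene network built directly from an edge table (r only)
toy_gcn <- function(nodes, edges_df) {
  edges_df$p_raw <- 0.001
  edges_df$q_fdr <- 0.01
  gene_network(nodes, edges_df)
}

toy_annotation <- function(...) {
  pathway_annotation(list(...))
}

# deterministic small two-group dataset for pipeline-level tests
small_planted_dataset <- function(seed = 11L, n_samples = 30L) {
  generate_dataset(synthetic_config(
    n_pathways = 5L, genes_per_pathway = 6L,
    n_samples_focal = n_samples, n_samples_background = n_samples,
    rho_within = 0.8,
    planted_cross_edges = list(list(pair = c("PW01", "PW03"),
                                    rho_cross = 0.8, focal_only = TRUE)),
    overlap_fraction = 0, seed = seed))
}

write_pipeline_inputs <- function(ds, dir, drugs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(ds$matrix, file.path(dir, "expression.tsv"))
  write_grouping(ds$grouping, file.path(dir, "groups.tsv"))
  write_gene_sets(ds$annotation, file.path(dir, "pathways.gmt"),
                  file.path(dir, "categories.tsv"))
  if (!is.null(drugs)) write_drug_map(drugs, file.path(dir, "drugs.tsv"))
  list(expression = file.path(dir, "expression.tsv"),
       groups = file.path(dir, "groups.tsv"),
       gmt = file.path(dir, "pathways.gmt"),
       categories = file.path(dir, "categories.tsv"),
       drugs = if (!is.null(drugs)) file.path(dir, "drugs.tsv"))
}
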