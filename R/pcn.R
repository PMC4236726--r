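pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Aggregate a gene network into a pathway network
#'
#' Every gene edge (g1, g2, r) contributes its correlation once to each
#' unordered pathway pair \{P, Q\}, P != Q, with P a pathway of one endpoint
#' and Q a pathway of the other (deduplicated per gene edge). A pathway
#' edge's weight is the arithmetic mean of its contributing gene-edge
#' correlations; `n_gene_edges` is their count. Genes without annotation
#' contribute nothing; pathway nodes are all pathways touched by at least one
#' surviving gene. Self-pairs (P = P) are excluded: only between-pathway
#' crosstalk is modelled.
#'
#' @param gcn A `gene_network`.
#' @param annotation A `pathway_annotation`.
#' @return A `pathway_network` with `p_perm` unset (NA).
#' @export
aggregate_pathway_edges <- function(gcn, annotation) {
  stopifnot(inherits(gcn, "gene_network"),
            inherits(annotation, "pathway_annotation"))
  gene2pw <- gene_to_pathways(annotation)
  covered <- intersect(gcn$nodes, names(gene2pw))
  if (!length(covered)) stop("no annotated gene present in the gene network")
  nodes <- sort(unique(unlist(gene2pw[covered], use.names = FALSE)))
  e <- gcn$edges
  if (nrow(e)) {
    pwA <- gene2pw[e$gene_a]
    pwB <- gene2pw[e$gene_b]
    pwA[vapply(pwA, is.null, logical(1L))] <- list(character(0))
    pwB[vapply(pwB, is.null, logical(1L))] <- list(character(0))
    nA <- lengths(pwA); nB <- lengths(pwB)
    # cross join per edge, fully vectorized: P cycles each annotation of the
    # first endpoint nB times; Q tiles the second endpoint's annotations nA times
    P <- rep(unlist(pwA, use.names = FALSE), times = rep(nB, times = nA))
    Q <- unlist(pwB[rep.int(seq_len(nrow(e)), nA)], use.names = FALSE)
    eidx <- rep.int(seq_len(nrow(e)), nA * nB)
    ok <- P != Q
    P <- P[ok]; Q <- Q[ok]; eidx <- eidx[ok]
    key <- pair_key(P, Q)
    dup <- duplicated(paste(eidx, key, sep = "\r"))  # once per gene edge
    key <- key[dup == FALSE]
    eidx <- eidx[dup == FALSE]
  } else key <- character(0)
  if (length(key)) {
    rsum <- rowsum(e$r[eidx], key)
    cnt <- as.vector(table(key)[rownames(rsum)])
    parts <- strsplit(rownames(rsum), "|", fixed = TRUE)
    edges <- data.frame(
      pathway_a = vapply(parts, `[[`, character(1L), 1L),
      pathway_b = vapply(parts, `[[`, character(1L), 2L),
      weight = as.vector(rsum) / cnt,
      n_gene_edges = cnt)
  } else {
    edges <- data.frame(pathway_a = character(0), pathway_b = character(0),
                        weight = numeric(0), n_gene_edges = integer(0))
  }
  pathway_network(nodes, edges)
}

gene_to_pathways <- function(annotation) {
  pg <- annotation$pathway_genes
  g <- unlist(pg, use.names = FALSE)
  p <- rep(names(pg), lengths(pg))
  lapply(split(p, g), unique)
}

# deterministic per-replicate seed; kept below 2^31
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 1e6) * 2039 + r * 7919) %% 2147483629L
}

run_gcn_pcn <- function(matrix, samples, annotation, alpha, r_threshold) {
  x <- matrix[, samples, drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  x <- x[sds > 0, , drop = FALSE]  # constant genes carry no correlation signal
  if (nrow(x) < 2L) return(NULL)
  cp <- pearson_all_pairs(x)
  gcn <- build_gcn(cp$r, cp$p, alpha = alpha, r_threshold = r_threshold)
  aggregate_pathway_edges(gcn, annotation)
}

#' Build the permutation null ensemble for pathway-edge significance
#'
#' The pooled matrix combines the focal cancer group with its matched
#' background group. For each of `R` replicates, `m` samples are drawn
#' without replacement as pseudo-focal labels and the full GCN-to-PCN
#' pipeline (same alpha, |r| threshold and gene list) is recomputed on them.
#' A pathway pair with no contributing gene edge in a replicate has null
#' weight 0. Replicate `r` uses a seed derived deterministically from
#' `(seed, r)`, so the ensemble is reproducible bit for bit.
#'
#' @param pooled Numeric genes x samples matrix pooling both groups.
#' @param m Focal group size (pseudo-cancer label count per replicate).
#' @param annotation A `pathway_annotation`.
#' @param alpha,r_threshold Gene-network parameters, matching the observed run.
#' @param R Number of replicates (default 150).
#' @param seed Master integer seed.
#' @param grouping Optional named group-label vector, recorded for provenance.
#' @return A `null_ensemble`: list with `R`, `seed`, `params`,
#'   `label_assignments` (list of sample-id vectors), `null_weights` (list of
#'   named numeric vectors keyed `"P|Q"`), and the pooled inputs for
#'   reduced-gene recomputation.
#' @export
permutation_null <- function(pooled, m, annotation, alpha = 0.05,
                             r_threshold = 0.5, R = 150L, seed = 1L,
                             grouping = NULL) {
  validate_expression(pooled)
  if (R < 1L) stop("R must be >= 1")
  if (m > ncol(pooled)) stop("m exceeds the pooled sample count")
  if (m < 3L) stop("m must be >= 3")
  assignments <- vector("list", R)
  weights <- vector("list", R)
  R <- as.integer(R)
  for (rep_i in seq_len(R)) {
    set.seed(derive_seed(seed, rep_i))
    lab <- sort(sample(colnames(pooled), m))
    assignments[[rep_i]] <- lab
    pcn <- run_gcn_pcn(pooled, lab, annotation, alpha, r_threshold)
    weights[[rep_i]] <- if (is.null(pcn) || !nrow(pcn$edges))
      stats::setNames(numeric(0), character(0))
    else stats::setNames(pcn$edges$weight,
                         pair_key(pcn$edges$pathway_a, pcn$edges$pathway_b))
  }
  structure(list(R = as.integer(R), seed = as.integer(seed),
                 params = list(alpha = alpha, r_threshold = r_threshold, m = m),
                 label_assignments = assignments, null_weights = weights,
                 pooled = pooled, annotation = annotation,
                 grouping = grouping),
            class = "null_ensemble")
}

null_weight_matrix <- function(null, keys) {
  out <- matrix(0, nrow = null$R, ncol = length(keys),
                dimnames = list(NULL, keys))
  for (i in seq_len(null$R)) {
    w <- null$null_weights[[i]]
    hit <- intersect(names(w), keys)
    if (length(hit)) out[i, hit] <- w[hit]
  }
  out
}

#' Assign permutation p-values to pathway edges
#'
#' Two-sided on the magnitude:
#' `p_perm = (1 + #\{replicates: |null weight| >= |observed weight|\}) / (R + 1)`
#' (add-one empirical p-value, so `p_perm >= 1/(R+1)` always). Edges with
#' `p_perm < alpha_pcn` are retained; others dropped. Isolated pathways stay
#' as nodes.
#'
#' @param observed A `pathway_network` from [aggregate_pathway_edges()].
#' @param null A `null_ensemble` built with the same annotation/parameters.
#' @param alpha_pcn Significance level (default 0.05, strict inequality).
#' @param keep_all If TRUE, return all edges with their p-values instead of
#'   dropping non-significant ones (used for calibration studies).
#' @return The filtered `pathway_network` with `p_perm` set.
#' @export
edge_significance <- function(observed, null, alpha_pcn = 0.05,
                              keep_all = FALSE) {
  stopifnot(inherits(observed, "pathway_network"),
            inherits(null, "null_ensemble"))
  e <- observed$edges
  if (!nrow(e)) return(observed)
  keys <- pair_key(e$pathway_a, e$pathway_b)
  nw <- null_weight_matrix(null, keys)
  exceed <- colSums(abs(nw) >= matrix(abs(e$weight), nrow = null$R,
                                      ncol = length(keys), byrow = TRUE))
  e$p_perm <- (1 + exceed) / (null$R + 1)
  if (!keep_all) e <- e[e$p_perm < alpha_pcn, , drop = FALSE]
  pathway_network(observed$nodes, e)
}

#' Empirical significance of a scalar network feature
#'
#' Add-one permutation p-values for an observed feature against its null
#' replicate values: `p_upper = (1 + #\{null >= obs\}) / (R + 1)`, `p_lower`
#' analogous, `p_two_sided = min(1, 2 * min(p_upper, p_lower))`.
#'
#' @param feature_values_null Numeric vector of the feature over replicates.
#' @param feature_observed Observed feature value.
#' @return List with `p_upper`, `p_lower`, `p_two_sided`.
#' @export
feature_significance <- function(feature_values_null, feature_observed) {
  if (!length(feature_values_null)) stop("empty null feature vector")
  R <- length(feature_values_null)
  p_up <- (1 + sum(feature_values_null >= feature_observed)) / (R + 1)
  p_lo <- (1 + sum(feature_values_null <= feature_observed)) / (R + 1)
  list(p_upper = p_up, p_lower = p_lo,
       p_two_sided = min(1, 2 * min(p_up, p_lo)))
}

#' Persist a null ensemble as TSV + JSON sidecar
#'
#' The TSV holds one row per (replicate, pathway pair) weight; the sidecar
#' records R, the master seed, pipeline parameters and the per-replicate
#' label assignments, so edge significance can be recomputed from disk
#' without re-running permutations.
#'
#' @param null A `null_ensemble`.
#' @param weights_path Output TSV path.
#' @param meta_path Output JSON path.
#' @export
write_null_ensemble <- function(null, weights_path, meta_path) {
  rows <- lapply(seq_len(null$R), function(i) {
    w <- null$null_weights[[i]]
    if (!length(w)) return(NULL)
    data.frame(replicate = i, pair = names(w), weight = unname(w))
  })
  df <- do.call(rbind, c(rows, list(data.frame(replicate = integer(0),
                                               pair = character(0),
                                               weight = numeric(0)))))
  df$weight <- format_weight(df$weight)
  utils::write.table(df, weights_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(R = null$R, seed = null$seed, params = null$params,
               label_assignments = null$label_assignments)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(weights_path)
}

#' Reload a persisted null ensemble
#'
#' The reloaded object supports [edge_significance()] and
#' [feature_significance()]; it does not carry the pooled expression matrix,
#' so reduced-gene recomputation ([gene_deletion_impact()] with
#' `recompute_p = TRUE`) requires the in-memory ensemble.
#'
#' @param weights_path TSV written by [write_null_ensemble()].
#' @param meta_path JSON sidecar path.
#' @return A `null_ensemble` (without pooled data).
#' @export
read_null_ensemble <- function(weights_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.delim(weights_path, colClasses = c("integer", "character",
                                                       "numeric"))
  weights <- rep(list(stats::setNames(numeric(0), character(0))), meta$R)
  if (nrow(df)) {
    sp <- split(df, df$replicate)
    for (nm in names(sp))
      weights[[as.integer(nm)]] <- stats::setNames(sp[[nm]]$weight, sp[[nm]]$pair)
  }
  la <- meta$label_assignments
  if (is.matrix(la)) la <- lapply(seq_len(nrow(la)), function(i) la[i, ])
  structure(list(R = meta$R, seed = meta$seed, params = as.list(meta$params),
                 label_assignments = la, null_weights = weights,
                 pooled = NULL, annotation = NULL, grouping = NULL),
            class = "null_ensemble")
}

#' Recompute null weights on a reduced gene set
#'
#' Re-runs the permutation pipeline reusing the stored per-replicate label
#' assignments (identical permutations, so before/after p-values are
#' comparable) on the pooled matrix restricted to `genes`.
#'
#' @param null A `null_ensemble` holding its pooled matrix.
#' @param genes Character vector of gene ids to keep.
#' @return A `null_ensemble` with updated `null_weights`.
#' @export
recompute_null_weights <- function(null, genes) {
  stopifnot(inherits(null, "null_ensemble"))
  if (is.null(null$pooled))
    stop("this ensemble was reloaded from disk and has no pooled matrix")
  pooled <- null$pooled[intersect(rownames(null$pooled), genes), , drop = FALSE]
  out <- null
  for (i in seq_len(null$R)) {
    pcn <- run_gcn_pcn(pooled, null$label_assignments[[i]], null$annotation,
                       null$params$alpha, null$params$r_threshold)
    out$null_weights[[i]] <- if (is.null(pcn) || !nrow(pcn$edges))
      stats::setNames(numeric(0), character(0))
    else stats::setNames(pcn$edges$weight,
                         pair_key(pcn$edges$pathway_a, pcn$edges$pathway_b))
  }
  out$pooled <- pooled
  out
}
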