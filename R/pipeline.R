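#' Read a pipeline run configuration
#'
#' YAML key-value document whose keys mirror the [run_pipeline()] config
#' list; `overrides` (e.g. command-line flags) replace file values.
#'
#' @param path Path to a YAML config file.
#' @param overrides Named list of values overriding the file.
#' @return Config list for [run_pipeline()].
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

default_run_config <- function() {
  list(alpha_gcn = 0.05, r_threshold = 0.5, alpha_pcn = 0.05,
       permutations = 150L, abs_percentile = 0.10, var_percentile = 0.10,
       focal_group = "tumor", background_group = "nontumor",
       hub_k = 10L, seed = 1L)
}

require_cfg <- function(config, keys) {
  for (k in keys)
    if (is.null(config[[k]]))
      stop("config is missing required field '", k, "'")
}

#' Run the full co-expression pipeline
#'
#' Orchestrates, in order: read inputs, quantile normalization, low-signal
#' filtering, optional signature subsetting, gene network construction on
#' the focal group, pathway aggregation, permutation null ensemble on the
#' pooled focal + background samples, pathway-edge significance, network
#' features with permutation significance, 3-/4-node circle inventories,
#' category-circle grouping, and (when a drug map is given) the intervention
#' comparison table. Every artifact is written to `out_dir` together with a
#' manifest of parameters and counts; identical config and seed reproduce
#' identical outputs byte for byte.
#'
#' @param config Named list: paths `expression`, `groups`, `gmt`, optional
#'   `categories`, `drugs`, `signature`; parameters `focal_group`,
#'   `background_group`, `alpha_gcn` (0.05), `r_threshold` (0.5 or NULL),
#'   `alpha_pcn` (0.05), `permutations` (150), `abs_percentile` /
#'   `var_percentile` (0.10), `hub_k` (10), `seed`, and `out_dir`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`matrix`, `gcn`, `pcn`, `null`, `features`, ...) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  require_cfg(cfg, c("expression", "groups", "gmt", "out_dir"))
  for (k in c("expression", "groups", "gmt", "categories", "drugs", "signature"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("stage io_formats: input file for '", k, "' not found: ", cfg[[k]])
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  mat <- stage("io_formats", read_expression(cfg$expression))
  grouping <- stage("io_formats", read_grouping(cfg$groups))
  annotation <- stage("io_formats", read_gene_sets(cfg$gmt, cfg$categories))
  drug_map <- if (!is.null(cfg$drugs))
    stage("io_formats", read_drug_map(cfg$drugs)) else NULL
  missing <- setdiff(colnames(mat), names(grouping))
  if (length(missing))
    stop("stage io_formats: sample '", missing[1L], "' has no group label")

  mat <- stage("preprocess", quantile_normalize(mat))
  filt <- stage("preprocess",
                filter_low_signal(mat, cfg$abs_percentile, cfg$var_percentile))
  mat <- filt$matrix
  if (!is.null(cfg$signature)) {
    sig <- readLines(cfg$signature)
    sig <- sig[nzchar(sig)]
    mat <- stage("preprocess", subset_to_signature(mat, sig))
  }
  write_expression(mat, out("normalized_matrix.tsv"))
  write_filter_report(filt$report, out("filter_report.tsv"))

  focal_samples <- intersect(colnames(mat),
                             names(grouping)[grouping == cfg$focal_group])
  background_samples <- intersect(colnames(mat),
                                  names(grouping)[grouping == cfg$background_group])
  if (length(focal_samples) < 3L)
    stop("stage gcn: focal group '", cfg$focal_group, "' has < 3 samples")
  if (!length(background_samples))
    stop("stage pcn: background group '", cfg$background_group, "' is empty")
  message("pipeline: ", nrow(mat), " genes kept, ", length(focal_samples),
          " focal / ", length(background_samples), " background samples")

  cp <- stage("gcn", pearson_all_pairs(mat, focal_samples))
  gcn <- stage("gcn", build_gcn(cp$r, cp$p, alpha = cfg$alpha_gcn,
                                r_threshold = cfg$r_threshold))
  write_network(gcn, out("gcn_edges.tsv"), "edge_list")
  message("pipeline: gene network has ", length(gcn$nodes), " nodes, ",
          nrow(gcn$edges), " edges")

  pcn_raw <- stage("pcn", aggregate_pathway_edges(gcn, annotation))
  pooled <- mat[, c(focal_samples, background_samples), drop = FALSE]
  null <- stage("pcn", permutation_null(
    pooled, m = length(focal_samples), annotation = annotation,
    alpha = cfg$alpha_gcn, r_threshold = cfg$r_threshold,
    R = cfg$permutations, seed = cfg$seed,
    grouping = grouping[colnames(pooled)]))
  pcn <- stage("pcn", edge_significance(pcn_raw, null, cfg$alpha_pcn))
  write_network(pcn, out("pcn_edges.tsv"), "edge_list")
  write_network(pcn, out("pcn.graphml"), "graphml")
  write_null_ensemble(null, out("null_weights.tsv"), out("null_meta.json"))
  message("pipeline: pathway network has ", length(pcn$nodes), " nodes, ",
          nrow(pcn$edges), " significant edges")

  features <- stage("netstats", network_features(pcn))
  write_features(features, out("pcn_features.tsv"))
  feat_sig <- stage("netstats", null_feature_significance(pcn, null))
  utils::write.table(feat_sig, out("pcn_feature_significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tri <- stage("netstats", enumerate_circles(pcn, 3L))
  quad <- stage("netstats", enumerate_circles(pcn, 4L))
  write_circles(tri, out("circles3.tsv"))
  write_circles(quad, out("circles4.tsv"))
  catc <- stage("redundancy", categorize_circles(tri, annotation))
  write_category_circles(catc, out("category_circles.tsv"))
  message("pipeline: ", nrow(tri$circles), " 3-node and ",
          nrow(quad$circles), " 4-node circles")

  comparison <- NULL
  if (!is.null(drug_map) && length(drug_map) &&
      any(vapply(drug_map, function(t) any(t %in% pcn$nodes), logical(1L)))) {
    usable <- drug_map[vapply(drug_map, function(t) any(t %in% pcn$nodes),
                              logical(1L))]
    sets <- c(usable,
              list(top_hubs = top_hubs(pcn, min(cfg$hub_k, length(pcn$nodes)))))
    comparison <- stage("intervention",
                        compare_target_sets(pcn, sets, hub_k = cfg$hub_k))
    utils::write.table(comparison, out("intervention_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "pcnet",
    version = as.character(utils::packageVersion("pcnet")),
    parameters = cfg[c("alpha_gcn", "r_threshold", "alpha_pcn",
                       "permutations", "abs_percentile", "var_percentile",
                       "focal_group", "background_group", "hub_k", "seed")],
    counts = list(genes_kept = nrow(mat),
                  focal_samples = length(focal_samples),
                  background_samples = length(background_samples),
                  gcn_nodes = length(gcn$nodes), gcn_edges = nrow(gcn$edges),
                  pcn_nodes = length(pcn$nodes), pcn_edges = nrow(pcn$edges),
                  circles3 = nrow(tri$circles), circles4 = nrow(quad$circles)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(matrix = mat, grouping = grouping, annotation = annotation,
                 gcn = gcn, pcn = pcn, null = null, features = features,
                 circles3 = tri, circles4 = quad, category_circles = catc,
                 comparison = comparison, out_dir = cfg$out_dir))
}

#' Permutation significance of scalar pathway-network features
#'
#' For each null replicate, the replicate's pathway network skeleton (pairs
#' with at least one contributing gene edge) is rebuilt from the stored null
#' weights and its scalar features computed; the observed network's features
#' are then assigned add-one permutation p-values via
#' [feature_significance()].
#'
#' @param pcn Observed `pathway_network`.
#' @param null A `null_ensemble`.
#' @return data.frame: `feature`, `observed`, `null_mean`, `p_upper`,
#'   `p_lower`, `p_two_sided`.
#' @export
null_feature_significance <- function(pcn, null) {
  scalar_features <- function(net) {
    f <- network_features(net)
    c(n_edges = sum(f$degrees) / 2, edge_density = f$edge_density,
      avg_clustering = f$avg_clustering, avg_degree = mean(f$degrees),
      giant_size = length(f$giant))
  }
  obs <- scalar_features(pcn)
  nullf <- vapply(seq_len(null$R), function(i) {
    w <- null$null_weights[[i]]
    if (!length(w))
      return(scalar_features(pathway_network(pcn$nodes, data.frame(
        pathway_a = character(0), pathway_b = character(0),
        weight = numeric(0), n_gene_edges = integer(0)))))
    parts <- strsplit(names(w), "|", fixed = TRUE)
    edges <- data.frame(
      pathway_a = vapply(parts, `[[`, character(1L), 1L),
      pathway_b = vapply(parts, `[[`, character(1L), 2L),
      weight = unname(w), n_gene_edges = 1L)
    nodes <- union(pcn$nodes, unique(c(edges$pathway_a, edges$pathway_b)))
    scalar_features(pathway_network(nodes, edges))
  }, obs)
  rows <- lapply(names(obs), function(f) {
    s <- feature_significance(nullf[f, ], obs[[f]])
    data.frame(feature = f, observed = obs[[f]],
               null_mean = mean(nullf[f, ]), p_upper = s$p_upper,
               p_lower = s$p_lower, p_two_sided = s$p_two_sided)
  })
  do.call(rbind, rows)
}
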