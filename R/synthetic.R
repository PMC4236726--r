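#' Configuration for the synthetic two-group expression generator
#'
#' Defines a block-correlated multivariate normal emulating a tumor /
#' matched non-tumor microarray study: genes are grouped into pathways with
#' within-pathway correlation `rho_within`, optional planted cross-pathway
#' correlation blocks (present only in the focal group when `focal_only`),
#' independent noise elsewhere, and a fraction of genes shared between
#' adjacent pathways so multi-membership aggregation is exercised.
#'
#' @param n_pathways Number of pathways (default 6).
#' @param genes_per_pathway Genes per pathway (default 8).
#' @param n_samples_focal,n_samples_background Group sizes (default 50/50).
#' @param rho_within Within-pathway correlation in `[0, 1)` (default 0.8).
#' @param planted_cross_edges List of `list(pair = c(P, Q), rho_cross = x,
#'   focal_only = TRUE)` entries (default none).
#' @param noise_sd Marginal standard deviation (default 1).
#' @param overlap_fraction Fraction of each pathway's genes shared with the
#'   next pathway (default 0.1).
#' @param categories Category labels assigned round-robin to pathways.
#' @param baseline_range Range of per-gene baseline log intensities
#'   (default `c(6, 10)`).
#' @param seed Integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_pathways = 6L, genes_per_pathway = 8L,
                             n_samples_focal = 50L,
                             n_samples_background = 50L,
                             rho_within = 0.8,
                             planted_cross_edges = list(),
                             noise_sd = 1,
                             overlap_fraction = 0.1,
                             categories = c("Signal Transduction",
                                            "Immune System", "Metabolism"),
                             baseline_range = c(6, 10),
                             seed = 1L) {
  if (n_samples_focal < 3L || n_samples_background < 3L)
    stop("group sizes must be >= 3")
  if (rho_within < 0 || rho_within >= 1) stop("rho_within must lie in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (n_pathways < 2L) stop("need at least 2 pathways")
  for (pe in planted_cross_edges) {
    if (length(pe$pair) != 2L || pe$pair[1L] == pe$pair[2L])
      stop("planted edge must name two distinct pathways")
    if (pe$rho_cross < 0 || pe$rho_cross >= 1)
      stop("rho_cross must lie in [0, 1)")
  }
  structure(list(n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 n_samples_focal = as.integer(n_samples_focal),
                 n_samples_background = as.integer(n_samples_background),
                 rho_within = rho_within,
                 planted_cross_edges = planted_cross_edges,
                 noise_sd = noise_sd,
                 overlap_fraction = overlap_fraction,
                 categories = categories,
                 baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

synthetic_annotation <- function(config) {
  npw <- config$n_pathways
  gpp <- config$genes_per_pathway
  n_shared <- floor(config$overlap_fraction * gpp)
  pw_ids <- sprintf("PW%02d", seq_len(npw))
  genes <- vector("list", npw)
  counter <- 0L
  for (i in seq_len(npw)) {
    fresh <- sprintf("g%04d", counter + seq_len(gpp))
    counter <- counter + gpp
    genes[[i]] <- fresh
  }
  # adjacent pathways additionally share the first n_shared genes of the next
  if (n_shared > 0L) {
    for (i in seq_len(npw - 1L))
      genes[[i]] <- c(genes[[i]], genes[[i + 1L]][seq_len(n_shared)])
  }
  names(genes) <- pw_ids
  categ <- stats::setNames(
    rep(config$categories, length.out = npw), pw_ids)
  pathway_annotation(genes, categ)
}

synthetic_correlation <- function(config, annotation, focal) {
  all_genes <- sort(unique(unlist(annotation$pathway_genes, use.names = FALSE)))
  n <- length(all_genes)
  S <- matrix(0, n, n, dimnames = list(all_genes, all_genes))
  for (g in annotation$pathway_genes) {
    i <- match(g, all_genes)
    S[i, i] <- pmax(S[i, i], config$rho_within)
  }
  for (pe in config$planted_cross_edges) {
    if (isTRUE(pe$focal_only) && !focal) next
    ga <- match(annotation$pathway_genes[[pe$pair[1L]]], all_genes)
    gb <- match(annotation$pathway_genes[[pe$pair[2L]]], all_genes)
    S[ga, gb] <- pmax(S[ga, gb], pe$rho_cross)
    S[gb, ga] <- t(S[ga, gb])
  }
  diag(S) <- 1
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    bad <- if (length(config$planted_cross_edges))
      paste(vapply(config$planted_cross_edges,
                   function(pe) paste(pe$pair, collapse = "-"), character(1L)),
            collapse = ", ")
    else "within-pathway"
    stop("implied correlation matrix is not positive definite ",
         "(offending block(s): ", bad, "); keep rho_cross <= rho_within")
  }
  S
}

#' Generate a synthetic two-group expression dataset with known truth
#'
#' Samples both groups from zero-mean multivariate normals with the block
#' correlation structure implied by the config, adds per-gene baseline
#' log-intensities, and returns the expression matrix together with sample
#' grouping, pathway annotation and the planted ground truth. Identical
#' config and seed reproduce identical output bit for bit.
#'
#' @param config A `synthetic_config`.
#' @return List with `matrix` (genes x samples), `grouping` (named vector,
#'   `"tumor"` / `"nontumor"`), `annotation` (a `pathway_annotation`) and
#'   `truth` (list with `true_pathway_edges`, a data.frame of planted pairs).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  annotation <- synthetic_annotation(config)
  S_focal <- synthetic_correlation(config, annotation, focal = TRUE)
  S_bg <- synthetic_correlation(config, annotation, focal = FALSE)
  genes <- rownames(S_focal)
  set.seed(config$seed)
  baseline <- stats::runif(length(genes), config$baseline_range[1L],
                           config$baseline_range[2L])
  sigma2 <- config$noise_sd^2
  xf <- MASS::mvrnorm(config$n_samples_focal, mu = rep(0, length(genes)),
                      Sigma = S_focal * sigma2)
  xb <- MASS::mvrnorm(config$n_samples_background,
                      mu = rep(0, length(genes)), Sigma = S_bg * sigma2)
  vals <- t(rbind(xf, xb)) + baseline
  rownames(vals) <- genes
  colnames(vals) <- c(sprintf("T%03d", seq_len(config$n_samples_focal)),
                      sprintf("N%03d", seq_len(config$n_samples_background)))
  grouping <- stats::setNames(
    rep(c("tumor", "nontumor"),
        c(config$n_samples_focal, config$n_samples_background)),
    colnames(vals))
  planted <- if (length(config$planted_cross_edges)) {
    data.frame(
      pathway_a = vapply(config$planted_cross_edges,
                         function(pe) min(pe$pair), character(1L)),
      pathway_b = vapply(config$planted_cross_edges,
                         function(pe) max(pe$pair), character(1L)),
      rho_cross = vapply(config$planted_cross_edges,
                         function(pe) pe$rho_cross, numeric(1L)),
      focal_only = vapply(config$planted_cross_edges,
                          function(pe) isTRUE(pe$focal_only), logical(1L)))
  } else {
    data.frame(pathway_a = character(0), pathway_b = character(0),
               rho_cross = numeric(0), focal_only = logical(0))
  }
  list(matrix = vals, grouping = grouping, annotation = annotation,
       truth = list(true_pathway_edges = planted, annotation = annotation))
}

#' Generate a random drug -> targeted-pathway map
#'
#' @param ground_truth Truth list from [generate_dataset()] (provides the
#'   pathway universe via its annotation).
#' @param n_drugs Number of drugs (0 gives an empty map).
#' @param targets_per_drug Pathways per drug (must not exceed the number of
#'   pathways).
#' @param seed Integer seed; identical seed reproduces the map.
#' @return Named list: drug name -> character vector of pathway ids.
#' @export
generate_drug_map <- function(ground_truth, n_drugs, targets_per_drug,
                              seed = 1L) {
  pathways <- names(ground_truth$annotation$pathway_genes)
  if (targets_per_drug < 1L || targets_per_drug > length(pathways))
    stop("targets_per_drug must lie in [1, n_pathways]")
  if (n_drugs < 0L) stop("n_drugs must be >= 0")
  if (n_drugs == 0L) return(stats::setNames(list(), character(0)))
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n_drugs), function(i)
    sort(sample(pathways, targets_per_drug)))
  names(out) <- sprintf("drug%02d", seq_len(n_drugs))
  out
}
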