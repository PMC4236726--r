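#' All-pairs Pearson correlation with significance
#'
#' Computes the full symmetric correlation matrix over genes (rows) using the
#' given sample subset, and two-sided p-values from the exact t transform
#' `t = r * sqrt((n-2) / (1-r^2))` with `n - 2` degrees of freedom.
#'
#' @param matrix Numeric genes x samples matrix.
#' @param sample_subset Optional character vector of sample ids (default: all
#'   samples). At least 3 samples required.
#' @return List with `r` (correlation matrix, unit diagonal) and `p` (raw
#'   two-sided p-value matrix, NA on the diagonal), plus `n_samples`.
#' @export
pearson_all_pairs <- function(matrix, sample_subset = NULL) {
  validate_expression(matrix)
  if (is.null(sample_subset)) sample_subset <- colnames(matrix)
  missing <- setdiff(sample_subset, colnames(matrix))
  if (length(missing)) stop("unknown sample id '", missing[1L], "'")
  n <- length(sample_subset)
  if (n < 3L) stop("need at least 3 samples for correlation significance")
  x <- matrix[, sample_subset, drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene over the sample subset: '",
         rownames(x)[sds == 0][1L], "' (filter first)")
  r <- stats::cor(t(x))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  diag(p) <- NA_real_
  list(r = r, p = p, n_samples = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, take the running suffix minimum
#' of `p_(j) * m / j`, cap at 1, and return in input order. Thin validated
#' wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (q-values), same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Build a gene co-expression network
#'
#' FDR is computed over all distinct unordered gene pairs
#' (`m = n*(n-1)/2`); an edge is kept iff its BH-adjusted p-value is below
#' `alpha` and, when `r_threshold` is given, `|r| >= r_threshold`. All genes
#' are retained as nodes, including isolated ones.
#'
#' @param r Symmetric correlation matrix with gene dimnames.
#' @param p Symmetric raw p-value matrix conformable with `r`.
#' @param alpha FDR significance level (default 0.05).
#' @param r_threshold Optional absolute-correlation threshold (default 0.5;
#'   `NULL` disables it).
#' @return A `gene_network`.
#' @export
build_gcn <- function(r, p, alpha = 0.05, r_threshold = 0.5) {
  if (!isTRUE(all.equal(dim(r), dim(p))) || is.null(rownames(r)))
    stop("r and p must be conformable square matrices with gene dimnames")
  genes <- rownames(r)
  n <- length(genes)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  pv <- p[idx]
  rv <- r[idx]
  q <- bh_fdr(pv)
  keep <- q < alpha
  if (!is.null(r_threshold) && r_threshold > 0)
    keep <- keep & abs(rv) >= r_threshold
  edges <- data.frame(gene_a = genes[idx[keep, 1L]],
                      gene_b = genes[idx[keep, 2L]],
                      r = rv[keep], p_raw = pv[keep], q_fdr = q[keep])
  gene_network(genes, edges)
}

#' Remove a gene (and its incident edges) from a gene network
#'
#' Node removal only: correlations among the remaining genes are unchanged
#' and are not re-tested.
#'
#' @param gcn A `gene_network`.
#' @param gene Gene id present in the network.
#' @return The reduced `gene_network`.
#' @export
delete_gene <- function(gcn, gene) {
  stopifnot(inherits(gcn, "gene_network"))
  if (!gene %in% gcn$nodes) stop("unknown gene '", gene, "'")
  e <- gcn$edges
  e <- e[e$gene_a != gene & e$gene_b != gene, , drop = FALSE]
  gene_network(setdiff(gcn$nodes, gene), e)
}
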