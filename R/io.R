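#' Read a gene expression table
#'
#' Reads a tab-separated expression table (log-scale intensities) with sample
#' ids in the first row and gene ids in the first column, and validates it
#' strictly: ids must be unique and every body cell must parse as a finite
#' number.
#'
#' @param path Path to a TSV file. First row: sample ids; first column: gene
#'   ids; body: numeric values.
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames, row and column order preserved.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression table needs a header and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # tolerate an (empty or named) corner cell above the gene-id column
  n_body_cols <- length(fields[[2L]])
  sample_ids <- if (length(header) == n_body_cols) header[-1L] else header
  if (length(sample_ids) != n_body_cols - 1L)
    stop("header has ", length(sample_ids), " sample ids but body rows have ",
         n_body_cols - 1L, " value columns")
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  check_unique_ids(gene_ids, "gene")
  check_unique_ids(sample_ids, "sample")
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_body_cols)
      stop("row ", i + 1L, " ('", row[1L], "') has ", length(row),
           " fields, expected ", n_body_cols)
    x <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("non-numeric or missing value '", row[-1L][bad[1L]],
           "' at gene '", gene_ids[i], "' (row ", i + 1L, "), sample '",
           sample_ids[bad[1L]], "' (column ", bad[1L] + 1L, ")")
    vals[i, ] <- x
  }
  validate_expression(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param digits Decimal digits written (default 6).
#' @export
write_expression <- function(matrix, path, digits = 6L) {
  validate_expression(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1L, function(x)
    paste(formatC(x, digits = digits, format = "f"), collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

validate_expression <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must form a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  check_unique_ids(rownames(values), "gene")
  check_unique_ids(colnames(values), "sample")
  if (nrow(values) < 2L) stop("need at least 2 genes")
  if (ncol(values) < 3L) stop("need at least 3 samples")
  if (!all(is.finite(values))) stop("expression matrix contains non-finite values")
  invisible(values)
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(ids == "")) stop("empty ", what, " id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate ", what, " id: '", dup[1L], "'")
  invisible(ids)
}

#' Read sample group labels
#'
#' Two-column TSV (sample_id, group), no header. Returns a named character
#' vector mapping sample id to group label.
#'
#' @param path Path to the TSV file.
#' @return Named character vector (names = sample ids, values = group labels).
#' @export
read_grouping <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 2L) stop("grouping file must have exactly two columns")
  check_unique_ids(tab[[1L]], "sample")
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write sample group labels
#' @param grouping Named character vector (names = sample ids).
#' @param path Output path.
#' @export
write_grouping <- function(grouping, path) {
  utils::write.table(data.frame(sample_id = names(grouping), group = unname(grouping)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read pathway gene sets (GMT) plus a pathway category map
#'
#' GMT lines are `set_name<TAB>description<TAB>gene1<TAB>gene2...`. The
#' category file is a two-column TSV (pathway_id, category) without header;
#' pathways absent from it are labelled `"uncategorized"`.
#'
#' @param gmt_path Path to a GMT file.
#' @param category_path Optional path to the category TSV (NULL = none).
#' @return A `pathway_annotation`: list with `pathway_genes` (named list of
#'   character vectors) and `pathway_category` (named character vector).
#' @export
read_gene_sets <- function(gmt_path, category_path = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate pathway id in GMT: '", dup[1L], "'")
  genes <- lapply(fields, function(f) {
    g <- unique(f[-(1:2)])
    g <- g[nzchar(g)]
    if (length(f) < 3L || !length(g))
      stop("GMT pathway '", f[1L], "' has no member genes")
    g
  })
  names(genes) <- ids
  categ <- stats::setNames(rep("uncategorized", length(ids)), ids)
  if (!is.null(category_path)) {
    ct <- utils::read.delim(category_path, header = FALSE, colClasses = "character")
    if (ncol(ct) != 2L) stop("category file must have exactly two columns")
    known <- intersect(ct[[1L]], ids)
    categ[known] <- ct[[2L]][match(known, ct[[1L]])]
  }
  pathway_annotation(genes, categ)
}

#' Construct a pathway annotation object
#'
#' @param pathway_genes Named list: pathway id -> character vector of genes.
#' @param pathway_category Named character vector: pathway id -> category.
#'   Pathways missing a category get `"uncategorized"`.
#' @return A `pathway_annotation` object.
#' @export
pathway_annotation <- function(pathway_genes, pathway_category = NULL) {
  if (!length(pathway_genes) || is.null(names(pathway_genes)))
    stop("pathway_genes must be a non-empty named list")
  check_unique_ids(names(pathway_genes), "pathway")
  if (any(lengths(pathway_genes) == 0L))
    stop("pathway '", names(pathway_genes)[lengths(pathway_genes) == 0L][1L],
         "' has an empty gene set")
  categ <- stats::setNames(rep("uncategorized", length(pathway_genes)),
                           names(pathway_genes))
  if (!is.null(pathway_category)) {
    known <- intersect(names(pathway_category), names(categ))
    categ[known] <- pathway_category[known]
  }
  structure(list(pathway_genes = pathway_genes, pathway_category = categ),
            class = "pathway_annotation")
}

#' Write pathway gene sets as GMT (+ optional category TSV)
#' @param annotation A `pathway_annotation`.
#' @param gmt_path Output GMT path.
#' @param category_path Optional output category TSV path.
#' @export
write_gene_sets <- function(annotation, gmt_path, category_path = NULL) {
  lines <- vapply(names(annotation$pathway_genes), function(p)
    paste(c(p, "na", annotation$pathway_genes[[p]]), collapse = "\t"),
    character(1L))
  writeLines(lines, gmt_path)
  if (!is.null(category_path))
    utils::write.table(
      data.frame(pathway = names(annotation$pathway_category),
                 category = unname(annotation$pathway_category)),
      category_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(gmt_path)
}

#' Read a drug -> targeted-pathway map
#'
#' Two-column TSV (drug, pathway_id), one row per pair, no header. Pathways
#' need not all exist in a given network; resolution happens at use time.
#'
#' @param path Path to the TSV file.
#' @return Named list: drug name -> character vector of pathway ids.
#' @export
read_drug_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 2L) stop("drug map must have exactly two columns")
  m <- lapply(split(tab[[2L]], tab[[1L]]), unique)
  if (any(lengths(m) == 0L)) stop("drug with empty target set")
  m
}

#' Write a drug -> pathway map
#' @param drug_map Named list of pathway id vectors.
#' @param path Output path.
#' @export
write_drug_map <- function(drug_map, path) {
  df <- data.frame(drug = rep(names(drug_map), lengths(drug_map)),
                   pathway = unlist(drug_map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 6 decimal digits: the package's documented serialization precision
format_weight <- function(x) formatC(x, digits = 6L, format = "f")

#' Write a network to disk
#'
#' Edge lists are tab-separated with one unordered pair per row
#' (`node_a < node_b` lexicographically) and weights at 6 decimal digits, so
#' a write/read round trip reproduces the edge set and weights exactly at
#' that precision. GraphML output is produced via igraph and loads in
#' Cytoscape.
#'
#' @param network A `gene_network` or `pathway_network`.
#' @param path Output path.
#' @param format `"edge_list"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, c("gene_network", "pathway_network")))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
    return(invisible(path))
  }
  e <- network$edges
  if (inherits(network, "gene_network")) {
    header <- c("gene_a", "gene_b", "r", "p_raw", "q_fdr")
    rows <- paste(e$gene_a, e$gene_b, format_weight(e$r),
                  format_weight(e$p_raw), format_weight(e$q_fdr), sep = "\t")
  } else {
    header <- c("pathway_a", "pathway_b", "weight", "n_gene_edges", "p_perm")
    pp <- if (is.null(e$p_perm)) rep(NA_real_, nrow(e)) else e$p_perm
    rows <- paste(e$pathway_a, e$pathway_b, format_weight(e$weight),
                  e$n_gene_edges, format_weight(pp), sep = "\t")
  }
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Path to the edge-list TSV.
#' @param nodes Optional full node set (to restore isolated nodes).
#' @return A `gene_network` or `pathway_network`, decided from the header.
#' @export
read_network <- function(path, nodes = NULL) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (identical(names(tab)[1:2], c("gene_a", "gene_b"))) {
    nd <- if (is.null(nodes)) sort(unique(c(tab$gene_a, tab$gene_b))) else nodes
    gene_network(nd, tab)
  } else if (identical(names(tab)[1:2], c("pathway_a", "pathway_b"))) {
    nd <- if (is.null(nodes)) sort(unique(c(tab$pathway_a, tab$pathway_b))) else nodes
    pathway_network(nd, tab)
  } else stop("unrecognized edge-list header: ", paste(names(tab), collapse = ", "))
}
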