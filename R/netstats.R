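#' Topological features of a network
#'
#' All metrics are computed on the undirected, unweighted skeleton: node
#' degrees and their distribution, edge density, local and average clustering
#' coefficients, connected components and the giant component. Isolated
#' nodes have degree 0 and local clustering 0.
#'
#' @param network A `gene_network` or `pathway_network`.
#' @return List with `degrees`, `degree_distribution`, `edge_density`,
#'   `local_clustering`, `avg_clustering`, `components` (list of node sets,
#'   ordered by decreasing size) and `giant` (largest component; size ties
#'   broken by lexicographically smallest member).
#' @export
network_features <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n == 0L) stop("network has no nodes")
  deg <- igraph::degree(g)
  dd <- table(deg) / n
  dens <- if (n < 2L) 0 else igraph::ecount(g) / (n * (n - 1) / 2)
  lc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(lc) <- names(deg)
  comp <- igraph::components(g)
  comps <- split(names(deg), comp$membership)
  comps <- lapply(comps, sort)
  smallest <- vapply(comps, `[[`, character(1L), 1L)
  comps <- comps[order(-lengths(comps), smallest)]
  names(comps) <- NULL
  list(degrees = deg,
       degree_distribution = stats::setNames(as.vector(dd), names(dd)),
       edge_density = dens,
       local_clustering = lc,
       avg_clustering = mean(lc),
       components = comps,
       giant = comps[[1L]])
}

#' Highest-degree nodes (hubs)
#'
#' @param network A `gene_network` or `pathway_network`.
#' @param k Number of hubs to return (>= 1); if `k` exceeds the node count
#'   all nodes are returned. Degree ties are broken lexicographically by
#'   node id.
#' @return Ordered character vector of node ids.
#' @export
top_hubs <- function(network, k) {
  if (k < 1L) stop("k must be >= 1")
  deg <- igraph::degree(as_igraph(network))
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(min(k, length(deg)))]
}

# canonical form of a simple cycle: among all rotations/reflections, the
# lexicographically smallest node sequence (starts at the smallest node and
# proceeds toward its smaller neighbor)
canonical_cycle <- function(nodes) {
  L <- length(nodes)
  best <- NULL
  for (dir in list(nodes, rev(nodes))) {
    for (s in seq_len(L)) {
      cand <- dir[((seq_len(L) + s - 2L) %% L) + 1L]
      if (is.null(best) ||
          paste(cand, collapse = "\r") < paste(best, collapse = "\r"))
        best <- cand
    }
  }
  best
}

#' Enumerate simple cycles of length 3 or 4
#'
#' Length-3 circles are triangles (mutually adjacent node triples). Length-4
#' circles are simple 4-cycles, chords permitted, each reported once in
#' canonical form (rotation/reflection invariant: starts at the
#' lexicographically smallest node and proceeds toward its smaller neighbor).
#'
#' @param network A `gene_network` or `pathway_network`.
#' @param length Cycle length, 3 or 4.
#' @return List with `length` and `circles`, a character matrix with one
#'   canonical cycle per row (0-row matrix when none), rows sorted.
#' @export
enumerate_circles <- function(network, length) {
  if (!length %in% c(3L, 4L)) stop("circle length must be 3 or 4")
  g <- as_igraph(network)
  empty <- matrix(character(0), ncol = length)
  if (length == 3L) {
    tri <- igraph::triangles(g)
    if (!base::length(tri)) return(list(length = 3L, circles = empty))
    m <- matrix(igraph::V(g)$name[tri], ncol = 3L, byrow = TRUE)
    m <- t(apply(m, 1L, sort))  # canonical triangle = sorted triple
  } else {
    el <- igraph::as_edgelist(g)
    adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                  function(v) v$name)
    names(adj) <- igraph::V(g)$name
    nodes <- sort(igraph::V(g)$name)
    rows <- list()
    # a 4-cycle u-v-w-x is determined by a diagonal pair {u,w} plus an
    # unordered pair of their common neighbors; dedupe via canonical form
    if (base::length(nodes) >= 4L) {
      for (i in seq_len(base::length(nodes) - 1L)) {
        u <- nodes[i]
        for (w in nodes[(i + 1L):base::length(nodes)]) {
          com <- intersect(adj[[u]], adj[[w]])
          com <- setdiff(com, c(u, w))
          if (base::length(com) < 2L) next
          cmb <- utils::combn(sort(com), 2L)
          for (j in seq_len(ncol(cmb)))
            rows[[base::length(rows) + 1L]] <-
              canonical_cycle(c(u, cmb[1L, j], w, cmb[2L, j]))
        }
      }
    }
    if (!base::length(rows)) return(list(length = 4L, circles = empty))
    m <- unique(do.call(rbind, rows))
  }
  ord <- if (length == 4L) order(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
         else order(m[, 1L], m[, 2L], m[, 3L])
  m <- m[ord, , drop = FALSE]
  dimnames(m) <- NULL
  list(length = as.integer(length), circles = m)
}

#' Export a feature bundle as flat key-value TSV
#' @param features List from [network_features()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  kv <- c(n_nodes = length(features$degrees),
          n_edges = sum(features$degrees) / 2,
          edge_density = features$edge_density,
          avg_clustering = features$avg_clustering,
          avg_degree = mean(features$degrees),
          n_components = length(features$components),
          giant_size = length(features$giant))
  utils::write.table(data.frame(feature = names(kv), value = unname(kv)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a circle set, one canonical cycle per row
#' @param circles List from [enumerate_circles()].
#' @param path Output path.
#' @export
write_circles <- function(circles, path) {
  m <- circles$circles
  lines <- if (nrow(m)) apply(m, 1L, paste, collapse = "\t") else character(0)
  writeLines(c(paste(paste0("v", seq_len(circles$length)), collapse = "\t"),
               lines), path)
  invisible(path)
}
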