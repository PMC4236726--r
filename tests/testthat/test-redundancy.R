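# small deterministic ensemble whose null weights never exceed the toys'
# observed weights, so every aggregated edge stays significant
permissive_null <- function(R = 39) {
  structure(list(R = R, seed = 1L,
                 params = list(alpha = 0.05, r_threshold = 0.5, m = 3L),
                 label_assignments = as.list(seq_len(R)),
                 null_weights = rep(list(stats::setNames(numeric(0),
                                                         character(0))), R),
                 pooled = NULL, annotation = NULL, grouping = NULL),
            class = "null_ensemble")
}

test_that("deleting an edgeless or unannotated gene leaves the PCN identical", {
  ann <- toy_annotation(P = "g1", Q = "g2")
  gcn <- toy_gcn(c("g1", "g2", "g3"),
                 data.frame(gene_a = "g1", gene_b = "g2", r = 0.8))
  rep <- gene_deletion_impact(gcn, ann, permissive_null(), "g3", "P",
                              recompute_p = FALSE)
  expect_identical(rep$degree_before, rep$degree_after)
  expect_identical(rep$pcn_before$edges, rep$pcn_after$edges)

  # unannotated but connected gene: its edges touch no pathway pair
  gcn2 <- toy_gcn(c("g1", "g2", "gx"), data.frame(
    gene_a = c("g1", "g1"), gene_b = c("g2", "gx"), r = c(0.8, 0.9)))
  rep2 <- gene_deletion_impact(gcn2, ann, permissive_null(), "gx", "P",
                               recompute_p = FALSE)
  expect_identical(rep2$pcn_before$edges, rep2$pcn_after$edges)
})

test_that("deleting the only bridging gene removes the crosstalk edge", {
  ann <- toy_annotation(P = "g1", Q = "g2", S = c("g3", "g4"))
  gcn <- toy_gcn(paste0("g", 1:4), data.frame(
    gene_a = c("g1", "g1"), gene_b = c("g2", "g3"), r = c(0.8, 0.7)))
  rep <- gene_deletion_impact(gcn, ann, permissive_null(), "g2", "P",
                              recompute_p = FALSE)
  expect_identical(rep$degree_before, 2L)
  expect_identical(rep$degree_after, 1L)
  gone <- rep$changed_edges[rep$changed_edges$pathway_b == "Q", ]
  expect_equal(gone$weight_before, 0.8)
  expect_true(is.na(gone$weight_after))
  expect_error(gene_deletion_impact(gcn, ann, permissive_null(), "nope", "P"),
               "unknown gene")
  expect_error(gene_deletion_impact(gcn, ann, permissive_null(), "g1", "ZZ"),
               "unknown pathway")
})

test_that("deletion can move a pathway weight in either direction", {
  # g2 contributes r = 0.2 to P-Q whose other contribution is 0.8:
  # deleting g2 raises the weight from 0.5 to 0.8
  ann <- toy_annotation(P = c("g1", "g3"), Q = c("g2", "g4"))
  gcn <- toy_gcn(paste0("g", 1:4), data.frame(
    gene_a = c("g1", "g3"), gene_b = c("g2", "g4"), r = c(0.2, 0.8)))
  rep <- gene_deletion_impact(gcn, ann, permissive_null(), "g2", "P",
                              recompute_p = FALSE)
  expect_equal(rep$changed_edges$weight_before, 0.5)
  expect_equal(rep$changed_edges$weight_after, 0.8)
  # and deleting the strong contributor lowers it to 0.2
  rep2 <- gene_deletion_impact(gcn, ann, permissive_null(), "g4", "P",
                               recompute_p = FALSE)
  expect_equal(rep2$changed_edges$weight_after, 0.2)
})

test_that("n_gene_edges never increases under any single-gene deletion", {
  set.seed(411)
  for (i in 1:10) {
    genes <- paste0("g", sprintf("%02d", 1:12))
    ann <- pathway_annotation(stats::setNames(
      lapply(1:4, function(k) sample(genes, sample(3:6, 1))),
      paste0("PW", 1:4)))
    pairs <- utils::combn(genes, 2)
    keep <- stats::runif(ncol(pairs)) < 0.35
    gcn <- toy_gcn(genes, data.frame(
      gene_a = pairs[1, keep], gene_b = pairs[2, keep],
      r = stats::runif(sum(keep), -1, 1)))
    before <- aggregate_pathway_edges(gcn, ann)
    kb <- pcnet:::pair_key(before$edges$pathway_a, before$edges$pathway_b)
    victim <- sample(genes, 1)
    reduced <- delete_gene(gcn, victim)
    if (!any(reduced$nodes %in% unlist(ann$pathway_genes))) next
    after <- aggregate_pathway_edges(reduced, ann)
    ka <- pcnet:::pair_key(after$edges$pathway_a, after$edges$pathway_b)
    expect_true(all(ka %in% kb))
    shared <- intersect(ka, kb)
    expect_true(all(after$edges$n_gene_edges[match(shared, ka)] <=
                    before$edges$n_gene_edges[match(shared, kb)]))
  }
})

test_that("deletion p-values reuse the stored permutation assignments", {
  ds <- small_planted_dataset(seed = 31, n_samples = 10)
  focal <- names(ds$grouping)[ds$grouping == "tumor"]
  cp <- pearson_all_pairs(ds$matrix, focal)
  gcn <- build_gcn(cp$r, cp$p)
  null <- permutation_null(ds$matrix, m = length(focal),
                           annotation = ds$annotation, R = 10, seed = 17)
  victim <- intersect(ds$annotation$pathway_genes$PW01, gcn$nodes)[1]
  rep1 <- gene_deletion_impact(gcn, ds$annotation, null, victim, "PW01")
  rep2 <- gene_deletion_impact(gcn, ds$annotation, null, victim, "PW01")
  # identical permutations, identical p-values: no fresh Monte-Carlo noise
  expect_identical(rep1$changed_edges, rep2$changed_edges)
  expect_identical(rep1$degree_after, rep2$degree_after)
})

test_that("circles_on_edge matches an exhaustive triple scan", {
  k4 <- adjacency_to_pathway_network(matrix(1L, 4, 4,
    dimnames = list(paste0("P", 1:4), paste0("P", 1:4))) - diag(1L, 4))
  expect_identical(circles_on_edge(k4, "P1", "P2"), c("P3", "P4"))

  star <- pathway_network(c("hub", "l1", "l2"), data.frame(
    pathway_a = rep("hub", 2), pathway_b = c("l1", "l2"),
    weight = 0.5, n_gene_edges = 1L))
  expect_identical(circles_on_edge(star, "hub", "l1"), character(0))
  expect_error(circles_on_edge(star, "l1", "l2"), "no edge")

  set.seed(412)
  for (i in 1:30) {
    a <- random_adjacency(sample(5:10, 1), 0.5)
    net <- adjacency_to_pathway_network(a)
    if (!nrow(net$edges)) next
    j <- sample(nrow(net$edges), 1)
    u <- net$edges$pathway_a[j]; v <- net$edges$pathway_b[j]
    brute <- sort(rownames(a)[a[u, ] == 1L & a[v, ] == 1L])
    expect_identical(circles_on_edge(net, u, v), brute)
  }
})

test_that("category circles group by sorted multiset and conserve totals", {
  ann <- pathway_annotation(
    list(P1 = "g1", P2 = "g2", P3 = "g3", P4 = "g4"),
    c(P1 = "c1", P2 = "c1", P3 = "c2", P4 = "c2"))
  circ <- list(length = 3L,
               circles = rbind(c("P1", "P2", "P3"), c("P1", "P2", "P4"),
                               c("P1", "P3", "P4")))
  cc <- categorize_circles(circ, ann)
  expect_equal(sum(cc$count), 3)
  expect_identical(cc$count[1], 2L)  # (c1,c1,c2) twice
  expect_identical(unlist(cc[1, c("category_1", "category_2", "category_3")],
                          use.names = FALSE), c("c1", "c1", "c2"))
  # pathway without category entry participates as "uncategorized"
  ann2 <- pathway_annotation(list(P1 = "g1", P2 = "g2", P3 = "g3", P4 = "g4"),
                             c(P1 = "c1", P2 = "c1"))
  cc2 <- categorize_circles(circ, ann2)
  expect_true("uncategorized" %in% unlist(cc2[, 1:3]))
  expect_equal(sum(cc2$count), 3)
})

test_that("category grouping equals a hand tally on random circles", {
  set.seed(413)
  pws <- paste0("P", 1:8)
  ann <- pathway_annotation(
    stats::setNames(as.list(paste0("g", 1:8)), pws),
    stats::setNames(sample(c("A", "B", "C"), 8, replace = TRUE), pws))
  for (rep_i in 1:10) {
    trip <- t(replicate(5, sort(sample(pws, 3))))
    cc <- categorize_circles(list(length = 3L, circles = trip), ann)
    tally <- table(apply(trip, 1, function(r)
      paste(sort(unname(ann$pathway_category[r])), collapse = "|")))
    got <- stats::setNames(cc$count, paste(cc$category_1, cc$category_2,
                                           cc$category_3, sep = "|"))
    expect_identical(sort(got), sort(stats::setNames(as.integer(tally),
                                                     names(tally))))
  }
})
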