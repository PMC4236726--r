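test_that("pathway aggregation averages contributing gene-edge correlations", {
  ann <- toy_annotation(P = "g1", Q = "g2")
  g <- toy_gcn(c("g1", "g2"), data.frame(gene_a = "g1", gene_b = "g2", r = 0.6))
  p <- aggregate_pathway_edges(g, ann)
  expect_identical(nrow(p$edges), 1L)
  expect_equal(p$edges$weight, 0.6)
  expect_equal(p$edges$n_gene_edges, 1L)

  ann2 <- toy_annotation(P = c("g1", "g3"), Q = c("g2", "g4"))
  g2 <- toy_gcn(paste0("g", 1:4), data.frame(
    gene_a = c("g1", "g3"), gene_b = c("g2", "g4"), r = c(0.6, 0.8)))
  p2 <- aggregate_pathway_edges(g2, ann2)
  expect_equal(p2$edges$weight, 0.7)
  expect_equal(p2$edges$n_gene_edges, 2L)
})

test_that("multi-membership genes contribute each cross pair once, never self-pairs", {
  # g1 in {A,B}, g2 in {A,C}: pairs {A,B},{A,C},{B,C} each once; {A,A} excluded
  ann <- toy_annotation(A = c("g1", "g2"), B = "g1", C = "g2")
  g <- toy_gcn(c("g1", "g2"), data.frame(gene_a = "g1", gene_b = "g2", r = 0.5))
  p <- aggregate_pathway_edges(g, ann)
  expect_identical(nrow(p$edges), 3L)
  expect_setequal(paste(p$edges$pathway_a, p$edges$pathway_b),
                  c("A B", "A C", "B C"))
  expect_equal(p$edges$weight, rep(0.5, 3))
  expect_equal(p$edges$n_gene_edges, rep(1L, 3))
})

test_that("unannotated genes contribute nothing; fully unannotated network errors", {
  ann <- toy_annotation(P = "g1", Q = "g2")
  g <- toy_gcn(c("g1", "g2", "gx"), data.frame(
    gene_a = c("g1", "g1"), gene_b = c("g2", "gx"), r = c(0.6, 0.9)))
  p <- aggregate_pathway_edges(g, ann)
  expect_identical(nrow(p$edges), 1L)
  expect_equal(p$edges$weight, 0.6)
  g2 <- toy_gcn(c("ga", "gb"), data.frame(gene_a = "ga", gene_b = "gb", r = 1))
  expect_error(aggregate_pathway_edges(g2, ann), "no annotated gene")
})

test_that("aggregation equals the brute-force oracle on random toys", {
  set.seed(407)
  for (i in 1:60) {
    n_genes <- sample(5:20, 1)
    n_pw <- sample(2:6, 1)
    genes <- paste0("g", sprintf("%02d", 1:n_genes))
    ann <- pathway_annotation(stats::setNames(lapply(seq_len(n_pw), function(k)
      sample(genes, sample(2:max(2, n_genes %/% 2), 1))),
      paste0("PW", seq_len(n_pw))))
    pairs <- utils::combn(genes, 2)
    keep <- stats::runif(ncol(pairs)) < 0.3
    if (!any(keep)) next
    ed <- data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
                     r = stats::runif(sum(keep), -1, 1))
    gcn <- toy_gcn(genes, ed)
    got <- aggregate_pathway_edges(gcn, ann)
    want <- oracle_aggregate(gcn, ann)
    key <- paste(got$edges$pathway_a, got$edges$pathway_b, sep = "|")
    expect_identical(sort(key), sort(want$pair))
    ord <- match(want$pair, key)
    expect_equal(got$edges$weight[ord], want$weight, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got$edges$n_gene_edges[ord], want$n, ignore_attr = TRUE)
  }
})

test_that("permutation ensembles are reproducible and respect m", {
  ds <- small_planted_dataset(seed = 5, n_samples = 5)
  n1 <- permutation_null(ds$matrix, m = 5, annotation = ds$annotation,
                         R = 2, seed = 99)
  n2 <- permutation_null(ds$matrix, m = 5, annotation = ds$annotation,
                         R = 2, seed = 99)
  expect_identical(n1$label_assignments, n2$label_assignments)
  expect_identical(n1$null_weights, n2$null_weights)
  expect_length(n1$label_assignments, 2)
  expect_true(all(lengths(n1$label_assignments) == 5))
  n3 <- permutation_null(ds$matrix, m = 5, annotation = ds$annotation,
                         R = 2, seed = 100)
  expect_false(identical(n1$label_assignments, n3$label_assignments))
  expect_error(permutation_null(ds$matrix, m = 99, annotation = ds$annotation,
                                R = 2, seed = 1), "exceeds")
  expect_error(permutation_null(ds$matrix, m = 5, annotation = ds$annotation,
                                R = 0, seed = 1), "R must be")
})

test_that("edge significance follows the add-one two-sided formula", {
  obs <- pathway_network(c("P", "Q"), data.frame(
    pathway_a = "P", pathway_b = "Q", weight = 0.9, n_gene_edges = 3L))
  fake_null <- function(weights) {
    structure(list(R = length(weights), seed = 1L,
                   params = list(alpha = 0.05, r_threshold = 0.5, m = 3L),
                   label_assignments = as.list(seq_along(weights)),
                   null_weights = lapply(weights, function(w)
                     if (is.na(w)) stats::setNames(numeric(0), character(0))
                     else c("P|Q" = w)),
                   pooled = NULL, annotation = NULL, grouping = NULL),
              class = "null_ensemble")
  }
  # |obs| above all 150 nulls -> p = 1/151, kept
  null <- fake_null(stats::runif(150, -0.5, 0.5))
  sig <- edge_significance(obs, null)
  expect_equal(sig$edges$p_perm, 1 / 151)
  # negative observed weight: magnitude comparison
  obs_neg <- pathway_network(c("P", "Q"), data.frame(
    pathway_a = "P", pathway_b = "Q", weight = -0.9, n_gene_edges = 3L))
  expect_equal(edge_significance(obs_neg, null)$edges$p_perm, 1 / 151)
  # observed 0: every |null| >= 0 -> p = 1, dropped (isolated nodes kept)
  obs0 <- pathway_network(c("P", "Q"), data.frame(
    pathway_a = "P", pathway_b = "Q", weight = 0, n_gene_edges = 1L))
  sig0 <- edge_significance(obs0, null)
  expect_identical(nrow(sig0$edges), 0L)
  expect_setequal(sig0$nodes, c("P", "Q"))
  expect_equal(edge_significance(obs0, null, keep_all = TRUE)$edges$p_perm, 1)
  # p exactly alpha is dropped (strict inequality): 19 nulls, 1 exceeding
  null19 <- fake_null(c(0.95, stats::runif(18, 0, 0.1)))
  expect_equal(edge_significance(obs, null19, keep_all = TRUE)$edges$p_perm, 0.1)
  expect_identical(nrow(edge_significance(obs, null19, alpha_pcn = 0.1)$edges), 0L)
  # replicates where the pair is absent count as null weight 0
  null_abs <- fake_null(c(NA, NA, 0.95))
  expect_equal(edge_significance(obs, null_abs, keep_all = TRUE)$edges$p_perm,
               (1 + 1) / 4)
})

test_that("feature significance implements the add-one empirical p-values", {
  nulls <- seq(0, 1, length.out = 150)
  s <- feature_significance(nulls, 2)
  expect_equal(s$p_upper, 1 / 151)
  expect_equal(s$p_lower, 1)
  expect_equal(s$p_two_sided, 2 / 151)
  s2 <- feature_significance(rep(3, 10), 3)
  expect_equal(s2$p_upper, 1)
  expect_equal(s2$p_lower, 1)
  s3 <- feature_significance(stats::rnorm(99), 0)
  expect_gt(s3$p_two_sided, 0.5)
  expect_error(feature_significance(numeric(0), 1), "empty")
})

test_that("null ensembles persist and reload to identical significance", {
  ds <- small_planted_dataset(seed = 13, n_samples = 8)
  null <- permutation_null(ds$matrix, m = 8, annotation = ds$annotation,
                           R = 5, seed = 3)
  cp <- pearson_all_pairs(ds$matrix,
                          names(ds$grouping)[ds$grouping == "tumor"])
  pcn0 <- aggregate_pathway_edges(build_gcn(cp$r, cp$p), ds$annotation)
  wp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".json")
  write_null_ensemble(null, wp, mp)
  null2 <- read_null_ensemble(wp, mp)
  expect_identical(null2$R, null$R)
  s1 <- edge_significance(pcn0, null, keep_all = TRUE)
  s2 <- edge_significance(pcn0, null2, keep_all = TRUE)
  expect_equal(s2$edges$p_perm, s1$edges$p_perm)
  expect_equal(s2$edges$weight, s1$edges$weight)
})
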