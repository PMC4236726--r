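---
title: "Pathway co-expression networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway co-expression networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnet)
```

## The model

`pcnet` infers communication ("crosstalk") between biological pathways from
two-group expression data — typically tumor samples and matched non-tumor
samples — and quantifies the redundancy mechanisms that let such a network
absorb targeted perturbations.

The procedure has two layers.

**Gene layer.** For a chosen sample group, every pair of genes receives a
Pearson correlation $r_{ij}$ and a two-sided p-value from the exact
t-transform $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom. The
family of all $\binom{G}{2}$ pairs is adjusted by Benjamini–Hochberg, and a
gene edge is kept when its adjusted p-value falls below `alpha_gcn` and,
optionally, $|r| \ge$ `r_threshold`. Genes are nodes whether or not they
retain edges, so node counts reflect the full post-filtering gene list.

**Pathway layer.** Each surviving gene edge $(g_1, g_2, r)$ is translated to
every unordered pathway pair $\{P, Q\}$, $P \neq Q$, with $P$ annotating one
endpoint and $Q$ the other, counted once per gene edge. A pathway edge's
weight is the arithmetic mean of its contributing gene-edge correlations and
keeps its sign: negative crosstalk is as informative as positive. Because a
gene commonly annotates many pathways, a single gene edge can feed many
pathway pairs — which is exactly the multi-membership redundancy the method
is designed to expose. Self-pairs $\{P, P\}$ are excluded: the object of
study is between-pathway communication.

**Significance by permutation.** Observed pathway weights are compared to a
null ensemble built by pooling the two sample groups, drawing `m`
pseudo-focal samples without replacement (with `m` fixed to the focal group
size), and re-running the entire gene-to-pathway pipeline; this is repeated
`R` times (default 150). An edge's p-value is the add-one empirical tail
probability on the magnitude,

$$p = \frac{1 + \#\{\,b : |w^{(b)}| \ge |w_\mathrm{obs}|\,\}}{R + 1},$$

so $p \ge 1/(R+1)$ always and a pathway pair that a replicate fails to form
contributes null weight 0 (conservative: rarely-formed edges are penalized).
Edges with $p <$ `alpha_pcn` are retained. The same add-one construction
gives upper, lower and two-sided p-values for scalar network features
(edge count, density, clustering, giant-component size) against the per-replicate
null networks.

**Redundancy mechanisms.** Three levels are quantified:

1. *Redundant genes* — delete one gene, re-aggregate, and contrast a focal
   pathway's significant crosstalk partners before and after
   (`gene_deletion_impact()`).
2. *Redundant crosstalk paths* — for a pathway edge, every common neighbor
   of its endpoints closes one 3-node circle through it
   (`circles_on_edge()`); many circles mean many indirect routes that
   survive an attack on the direct edge.
3. *Redundant category circles* — 3-node circles reduced to the sorted
   multiset of their members' pathway categories (`categorize_circles()`):
   distinct circles drawn from the same biological systems are functionally
   interchangeable.

**Interventions.** A drug (or hub set, or category selection) is modeled as
simultaneous deletion of its targeted pathways. `remove_pathways()` reports
first-neighbor coverage, the fraction of edges incident to the targets, the
surviving node count, newly isolated pathways, post-deletion hubs, and the
fraction of 3-node circles containing at least one target;
`compare_target_sets()` tabulates several target sets against identical
denominators.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha_gcn` | 0.05 | BH-FDR level for gene edges (unitless probability) |
| `r_threshold` | 0.5 | minimum \|Pearson r\| for a gene edge; `NULL` disables |
| `alpha_pcn` | 0.05 | permutation level for pathway edges, strict (`p < alpha`) |
| `permutations` (R) | 150 | null replicates; the p-value floor is 1/(R+1) |
| `abs_percentile` | 0.10 | genes with mean expression strictly below this quantile are removed |
| `var_percentile` | 0.10 | likewise for across-sample variance; removal is the union |
| `m` | focal group size | pseudo-focal sample count per permutation, held fixed |
| `hub_k` | 10 | hubs reported per network, ties broken lexicographically |

The 0.05/0.5/150/10% defaults are the method's canonical operating point;
all are exposed through `run_pipeline()`'s config.

## The synthetic generator

`generate_dataset()` draws both groups from zero-mean multivariate normals
with unit variance and block correlation structure: `rho_within` (default
0.8) between genes sharing a pathway, planted `rho_cross` blocks between
chosen pathway pairs (restricted to the focal group when `focal_only`), and
independence elsewhere; per-gene baseline log-intensities are uniform on
6–10 so the low-signal filters have something to act on. A configurable
fraction of genes is shared between adjacent pathways because
multi-membership genes drive the aggregation rule; categories are assigned
round-robin so category-circle grouping is exercised. Identical config and
seed reproduce the dataset bit for bit.

Two modeling constraints are worth knowing. First, a planted cross-block
with `rho_cross > rho_within` makes the implied block covariance
non-positive-definite, so planted studies keep the two equal (0.8); the
constructor validates positive definiteness via a Cholesky attempt and
names the offending block otherwise. Second, the generator reproduces only
the property the pipeline consumes — correlation structure. It does not
emulate microarray noise physics (background, saturation, probe effects),
batch structure, outlier samples, or heavy-tailed expression, so passing
tests demonstrate correctness of the inference machinery, not robustness to
every artifact of real microarray data.

Default study conditions used by the test suite and the acceptance script:
recovery studies use 6 pathways × 8 genes with 50 samples per group and a
single focal-only planted edge at $\rho = 0.8$, assessed over 50 (suite) or
20 (script) independent pipeline replicates with $R = 150$; calibration
studies use 33 pathways × 4 genes (528 pathway pairs) with 25 samples per
group and no signal, run with `alpha_gcn = 1` and no $|r|$ threshold so
every pathway pair carries a defined weight in both the observed and null
networks — under the FDR filter a no-signal dataset has essentially no
edges and the calibration would be vacuous. Unit tests run on deliberately
small fixtures.

## Numerical choices and edge cases

- **Quantile normalization** is implemented directly: the reference is the
  vector of per-rank means of the sorted columns; each column's values are
  replaced positionally, and tied entries within a column receive the mean
  of the reference values at their tied ranks (the dialect `limma` uses for
  two-way ties). A consequence worth stating honestly: with ties, a
  column's output multiset contains that tie-group mean repeated rather
  than the distinct reference values, so exact sorted-column identity
  across columns — and with it exact idempotence — holds on tie-free
  matrices only. No tie-averaging dialect avoids this; the alternative
  (assigning tied entries the distinct reference values in positional
  order) would restore exact idempotence at the cost of making tied-value
  treatment order-dependent, and was rejected.
- **Filter quantiles** use R's inclusive linear-interpolation convention
  (type 7) with a strict "below" cut, so a gene exactly at the cut is kept.
  The two criteria are united by default (`combine = "intersection"` is
  available since the conjunction is a defensible alternative reading).
- **Filtering order**: normalization first, then filters, then correlation —
  this makes the variance filter scale-free; permutation replicates reuse
  the normalized matrix, since relabeling does not change a label-agnostic
  normalization.
- **Boundary conventions** are strict everywhere a level is named:
  `q < alpha_gcn`, `p_perm < alpha_pcn`; an edge at exactly 0.05 is dropped.
- **Circles** are simple cycles counted up to rotation and reflection,
  stored canonically (start at the lexicographically smallest node, proceed
  toward its smaller neighbor). Triangles coincide with sorted node
  triples; 4-cycles are enumerated via diagonal pairs and common neighbors,
  and chordful 4-cycles are counted (inclusive counting, stated and
  tested).
- **Determinism**: a single master seed; per-replicate seeds derive from
  `(seed, replicate)` and stay below $2^{31}$; hub and component ties break
  lexicographically; edge lists store each unordered pair once with
  `node_a < node_b` and serialize weights at 6 decimal digits, the
  documented round-trip precision.
- **Degenerate inputs** error early with coordinates: duplicate ids,
  non-numeric cells, zero-variance genes (before correlation), empty GMT
  member lists, all-genes-removed filters, empty signature intersections.

## Open design points, resolved

- *Expected vs observed pathway connectivity* (`hub_expectation()`): the
  question — are pathway hubs merely the pathways of gene hubs and/or the
  largest pathways? — needs a scoring rule, and none is canonical. The
  package ranks each pathway by the average of two ranks (sum of
  member-gene degrees in the gene network; member-gene count) and reports
  the discrepancy to the observed degree rank. This heuristic is isolated
  behind that single function.
- *Deletion p-values* reuse the stored permutation label assignments on the
  reduced gene set rather than drawing fresh permutations: before/after
  p-values then differ only through the deletion, not through Monte-Carlo
  noise.
- *Persisted null ensembles* (TSV of replicate weights + JSON sidecar with
  seed and label assignments) support recomputing edge significance without
  re-running permutations; recomputing deletion p-values additionally needs
  the pooled expression matrix, which only the in-memory ensemble carries.
- *Command-line use*: the package functions are the primary interface; a
  thin wrapper (`inst/cli/pcn.R`, subcommands `simulate` and `run`) drives
  `generate_dataset()` and `run_pipeline()` for shell use.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(
  planted_cross_edges = list(list(pair = c("PW01", "PW03"),
                                  rho_cross = 0.8, focal_only = TRUE)),
  seed = 1)
ds <- generate_dataset(cfg)

focal <- names(ds$grouping)[ds$grouping == "tumor"]
cp  <- pearson_all_pairs(quantile_normalize(ds$matrix), focal)
gcn <- build_gcn(cp$r, cp$p, alpha = 0.05, r_threshold = 0.5)
null <- permutation_null(ds$matrix, m = length(focal),
                         annotation = ds$annotation, R = 150, seed = 2)
pcn <- edge_significance(aggregate_pathway_edges(gcn, ds$annotation), null)
pcn$edges
```

## Known limitations

- Pearson correlation only; rank-based or information-theoretic edge
  definitions are out of scope.
- Identifier matching is exact and case-sensitive: no symbol aliasing or
  cross-database mapping. Annotation files are opaque inputs.
- Betweenness/bottleneck centrality is deliberately absent.
- Deletion is binary node removal; no partial knockdown, dose or synergy
  modeling.
- Permutation cost scales as `R` full pipeline runs; for genome-scale
  matrices, subset to a signature first (as the pipeline does).
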