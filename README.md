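# pcnet — protein co-expression networks from proteomic abundance matrices

`pcnet` builds and analyses **mutual-information protein co-expression
networks** (PCNs) from quantitative proteomics: a proteins × samples
matrix of log-ratio abundances, as produced by large tumor-profiling
studies, goes in; a significance-calibrated co-expression network with
hierarchical functional communities, differential-expression annotation
and chromosomal edge statistics comes out. It is aimed at computational
biologists who want the full transcriptome-style co-expression toolkit —
network inference, module detection, over-representation analysis,
topology statistics — at the protein level, with every stage testable
against planted ground truth.

## The method

**Edge statistic.** Co-expression between proteins *x* and *y* is their
mutual information, estimated nonparametrically by adaptive partitioning
on the copula transform: each protein's values are mapped to ranks
*r/N* ∈ (0,1], and the unit square is split recursively into quadrants
at cell midpoints. A cell holding *n* points is split while the
chi-square statistic of its quadrant counts against local uniformity,
*X² = Σ(obs − n/4)²/(n/4)*, exceeds 7.815 (the 95% point at 3 df) and
*n* ≥ 8; each leaf cell contributes *(n/N)·ln[(n/N)/area]*, and

> MI(x, y) = Σ_leaves (n/N) · ln[(n/N) / (Δx·Δy)]   (nats, floored at 0).

**Edge significance.** The null distribution of MI is calibrated by
permutation: ≥10⁵ random protein pairs with one member shuffled across
samples. P-values come from the empirical permutation survival function
where it is measurable and from a least-squares fit of
log₁₀ p(MI ≥ x) = a + b·x over the upper tail where extrapolation is
needed — stringent cutoffs such as p < 10⁻⁸ lie far below any empirical
quantile. Networks keep edges below a significance threshold, optionally
pruned by the data-processing inequality (weakest edge of each triangle)
and/or restricted to the top-k highest-MI edges.

**Communities.** Two-level hierarchy by greedy modularity maximisation
(*Q = Σ_i (e_ii − a_i²)*): agglomerative merging plus deterministic
refinements (single-node sweeps, recursive splits), then a second
partitioning pass inside every community, giving mutually exclusive
subcommunities `SC<c>_<k>`.

**Annotation.** Per-protein differential expression (tumor − healthy)
with empirical-Bayes variance moderation and BH-FDR; hypergeometric
over-representation of every subcommunity against GMT gene sets
(category window 5–2000); expression assortativity (fraction of a
subcommunity's edges joining proteins with the same log₂FC sign);
power-law fit of the log–log degree distribution; cis/trans chromosomal
edge classification and component sizes.

A synthetic-data generator plants nested correlated modules
(*x = λ·f_module + (λ/2)·g_submodule + ε*), tumor shifts, missingness
and chromosome assignments, so the whole pipeline is verifiable without
any data download.

## Worked example

```r
library(pcnet)

cfg <- synthetic_config(n_proteins = 120, n_tumor = 100, n_healthy = 3,
                        n_modules = 4, submodules_per_module = 1,
                        module_loading = 2, noise_sd = 1,
                        de_fraction = 0.2, missing_rate = 0.05, seed = 1)
ds <- generate_dataset(cfg)
ds$matrix
#> expr_matrix: 120 proteins x 103 samples, 565 missing (4.6%)
#>   groups: healthy=3, tumor=100

m <- impute_missing(filter_pgenes_by_missingness(ds$matrix, max_missing = 60))
tumors <- samples_in_group(m, "tumor")
ranked <- copula_rank_transform(m$values[, tumors], seed = 2)
null <- calibrate_null(ranked, n_perm = 1e5, seed = 3)
null
#> mi_null: log10 p = -0.425 + (-23.369) * MI  (R2 = 0.9960, 100000 permutations, N = 100)

net <- infer_network(ranked, null, p_thresh = 0.05 / choose(120, 2))
net
#> pcn_network: 120 nodes, 1325 edges

part <- subpartition(net, detect_communities(net))
adjusted_rand_index(ds$truth$module,
                    part$community[match(ds$truth$protein, part$protein)])
#> [1] 1

de <- de_analysis(m)
head(expression_assortativity(net, part, setNames(de$sign, de$protein)), 3)
#>   subcommunity n_edges    expass
#> 1        SC1_1     133 0.4586466
#> 2        SC1_2      78 0.8461538
#> 3        SC2_1     109 1.0000000
```

The four planted modules are recovered exactly (adjusted Rand index 1);
the null-model slope says MI must exceed ≈0.32 nats before an edge
reaches p < 10⁻⁸ at 100 samples; assortativity near 1 marks
subcommunities coherently over- or under-expressed, values near 0.5
mixed ones.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
and write their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | generate the planted study (matrix, metadata, chromosomes, gene sets) |
| `02_qc.R` | missingness filter, flagged-sample removal, healthy-completeness, imputation |
| `03_diffexp.R` | moderated-t differential expression |
| `04_network.R` | rank transform, null calibration, thresholded + top-k networks |
| `05_communities.R` | two-level communities, scored against planted truth |
| `06_enrichment.R` | subcommunity over-representation against the gene sets |
| `07_topology.R` | degree fit, assortativity, cis/trans, components |
| `08_compare.R` | function-driven vs location-driven network contrast |

Run them in order: `for f in analysis/0*.R; do Rscript "$f"; done`.
`run_pipeline()` performs stages 2–7 in one call with provenance capture.

## Vignette

`vignettes/protein-coexpression-networks.Rmd` documents the model and
its assumptions, all tunable parameters with defaults and rationale,
what the synthetic generator does and does not emulate, numerical
choices and known limitations.
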