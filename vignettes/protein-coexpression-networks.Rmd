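---
title: "Methods: mutual-information protein co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual-information protein co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnet)
```

## Scope and model

`pcnet` takes a quantitative proteomics matrix — gene-level protein
abundances ("pGenes") for on the order of 10⁴ proteins across ~10²
tumor and a handful of healthy samples — and derives from it a protein
co-expression network (PCN) together with its functional and
differential-expression annotation. Mutual information is used as the
co-expression measure because protein abundances frequently violate the
linearity assumption behind Pearson correlation; MI captures any
statistical dependence and is invariant under monotone transforms of
either variable.

The pipeline is a fixed sequence: quality control → differential
expression → MI network inference → two-level community detection →
subcommunity enrichment → topology statistics. Each stage is a pure
function of its inputs and a seed, so a run is bit-reproducible.

## Quality control

Three filters are applied in a fixed order, then imputation:

1. **Missingness cap** — proteins missing in more than `max_missing`
   samples (default 60, a sensible cap for a ~111-sample study;
   a fraction-based alternative is available for other widths) are
   dropped.
2. **Flagged samples** — samples marked in the metadata (e.g. evidence
   of protein decay) are removed. The flag list lives in the metadata
   file, not in code.
3. **Control completeness** — proteins not fully measured in the healthy
   group are dropped, because a 3-sample contrast anchor cannot tolerate
   further loss.
4. **Median imputation** — remaining gaps are filled with the protein's
   observed median. The co-expression estimator downstream is rank-based,
   so any monotone-neutral single-value imputation is equivalent there;
   the median is the order-statistics-friendly choice. Observed values
   are never altered, and the filters are idempotent.

Gene symbols are upper-cased on input so joins with chromosome maps and
gene-set collections are case-insensitive.

## Differential expression

Tumor vs healthy is the only contrast; no covariates are modelled. For
each protein the effect is the difference in group means (log₂ units)
with the pooled within-group variance s², df = n₁ + n₂ − 2. Variances
are moderated by a scaled inverse-chi-square prior fitted by method of
moments on e = log s² − ψ(df/2) + log(df/2):

- trigamma(d₀/2) = var(e) − trigamma(df/2)  (solved by Newton inversion),
- s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2)),

with d₀ = ∞ (full shrinkage) when the spread of log-variances does not
exceed its sampling expectation. The moderated statistic is
t = lfc / (s̃·√(1/n₁+1/n₂)) with s̃² = (d₀s₀² + df·s²)/(d₀ + df) on
d₀ + df degrees of freedom, two-sided p-values (sidedness is a
convention; two-sided is the conservative default), and BH-FDR. The
implementation follows these formulas directly and is cross-checked in
the test suite against an independent moderation implementation.

Each protein gets a binary expression sign: +1 when lfc ≥ 0, −1
otherwise. Mapping lfc = 0 to +1 is an arbitrary but documented
convention that keeps the label set binary for assortativity.

**Known limitation.** With 3 healthy samples, power is very limited, and
a module's shared latent variation can shift the whole module's
estimated fold change: in module-aligned synthetic regimes the
*estimated* sign of an entire module occasionally dilutes even when the
planted shift is large. Tests of the assortativity statistic therefore
use planted signs; the workflow reports the estimated-sign agreement so
the effect is visible rather than hidden.

## MI estimation

Each protein row is copula-transformed (rank/N with seeded jitter
tie-breaking; constant rows draw a random permutation with a warning).
MI is estimated by adaptive partitioning of the unit square: a cell with
n points is split at its midpoints into four quadrants while
X² = Σ(obs − n/4)²/(n/4) > `chi2_crit` (default 7.815, the 95% point of
χ²₃) and n ≥ `min_points` (default 8); leaves contribute
(n/N)·ln[(n/N)/area]; the sum is floored at 0. The root cell is always
split: the copula transform balances the root margins exactly, which
collapses the root chi-square test to a ~1-df statistic that almost
never fires, and without the forced split the null distribution is a
>99% atom at zero. Deeper cells have free margins and the standard rule
applies. The estimator is validated against the closed-form Gaussian
value −½ln(1−ρ²) to within 0.1 nats at N = 5000 for ρ up to 0.9, and
against an independent naive reimplementation of the recursion exactly.

## Edge significance

The null is built from permuted pairs: pick two random proteins, shuffle
one across samples, estimate MI; pool `n_perm` values (10⁵ by default —
at 100 samples this takes about a second). P-values use:

- the **empirical survival function** wherever at least 50 pooled values
  lie at or above the observed MI (so p(0) = 1 exactly, and moderate
  p-values are permutation-exact rather than model-based);
- the **fitted tail law** log₁₀ p = a + b·MI (least squares over the top
  5% of the pool) below that floor. Stringent thresholds — the
  conventional 10⁻⁸ cutoff at proteome scale — are reachable only by
  this extrapolation; the fit's R² is reported so a poor tail is
  visible.

Calibration is verified on fresh permutations: the realized edge rate at
p < 10⁻³ stays within 3 binomial standard errors of nominal.

**Threshold choice.** The pipeline default keeps edges at p < 10⁻⁸, the
conventional proteome-scale cutoff (it corresponds to family-wise
control at ~5×10⁷ pairs). The desk-scale studies in `analysis/` and the
acceptance script use the same construction logic expressed generically,
p < 0.05/n_pairs, because a fixed 10⁻⁸ at a few thousand pairs is far
more conservative than its full-scale rationale implies and (at 100
samples) its critical MI lands above the planted cross-submodule
dependence, severing the hierarchy the study is probing. Top-k selection
(default k = 10⁴, ties at the boundary kept and logged) mirrors the
"top 0.1% of interactions" views used for large networks.
Data-processing-inequality pruning (remove the strictly weakest edge of
every triangle, tolerance 0) is implemented but **off by default**; all
triangles are evaluated against the original MI values so the result is
scan-order independent.

## Community detection

Communities maximise unweighted Newman–Girvan modularity
Q = Σᵢ(eᵢᵢ − aᵢ²). The search is greedy and fully deterministic:

1. fast-greedy agglomeration (CNM);
2. single-node reassignment sweeps in lexicographic node order
   (first-improvement, incremental ΔQ);
3. recursive-split refinement: re-run the greedy pass inside every
   community, accept any split that raises global Q, then sweep again,
   until Q stops improving;
4. ties toward coarseness: if the result does not beat the
   connected-component partition (a clique ties at Q = 0), the
   components are returned. Isolated nodes form singleton communities.

Steps 2–3 exist because plain agglomeration is prone to over-merging
small communities; the refinements stay on the same objective and
guarantee the returned partition beats its single-merge and
single-split neighbours. Subcommunities re-run the same procedure on
each community's induced subgraph; labels are `SC<c>_<k>` with k
numbered by decreasing size, wholly contained in their community,
mutually exclusive and exhaustive.

On nested synthetics the level-1 planted modules are recovered at median
ARI ≥ 0.9 and level-2 submodules at median ARI ≥ 0.8 across five
generator seeds. Some realizations sit at an information limit rather
than an algorithmic one: the planted 3-way split can have *lower*
modularity than a 2-way merge for that draw, in which case no
modularity maximiser can recover it.

## Enrichment

Over-representation of each subcommunity uses the exact hypergeometric
upper tail (via the stable distribution-function implementation), with
the standard 5–2000 category-size window applied after intersecting
sets with the universe, and BH adjustment within each subcommunity's
tests (matching per-query web-tool behaviour; a global option exists).
Only subcommunities with ≥ 3 mapped genes are tested. The default
universe is the measured (post-QC) proteins intersected with the
collection's genes — using a genome-wide reference instead (available
via the `universe` argument) inflates significance by counting genes
that could never have been observed; both options are deliberate.
Because the universe choice dominates absolute p-values, published
absolute enrichment significances are not comparable targets; ranks and
patterns are.

## Topology statistics

- **Degree fit**: OLS of log₁₀(count) on log₁₀(degree) over histogram
  points with count > 0 — deliberately the plotted-fit convention used
  alongside degree plots, not maximum-likelihood tail estimation; both
  the signed Pearson r and |r| are reported. Block-structured synthetics
  are not scale-free, so the estimator is validated on an exactly
  constructed k^(−1.5) histogram (slope recovered to ±0.02) rather than
  on generator output.
- **Expression assortativity**: per subcommunity, the fraction of
  internal edges whose endpoints share a DE sign; reported only above a
  floor of >10 internal edges; invariant under global sign flips.
  Module-aligned signs drive it to 1, randomized signs to ~0.5 — the
  two regimes reproduce the bimodal pattern seen in real tumor PCNs.
- **cis/trans**: every edge is exactly one of cis (same chromosome),
  trans, or unmapped. With chromosomes assigned uniformly at random and
  independently of modules, the expected cis fraction is exactly
  1/n_chromosomes (pairwise indicators are uncorrelated, so the binomial
  standard error is exact); with module-aligned chromosomes it
  approaches 1. These regimes bracket the contrast between
  location-driven gene co-expression and function-driven protein
  co-expression.
- **Component sizes** from graph traversal, cross-checked against a
  union-find oracle in the tests.

## Synthetic data: what it does and does not emulate

`generate_dataset()` draws x_ps = λ·f_m(s) + (λ/2)·g_mk(s) + ε_ps with
standard-normal factors per module (f) and submodule (g) and noise sd σ.
Within-submodule correlation is (λ² + λ²/4)/(λ² + λ²/4 + σ²) and
cross-submodule, same-module correlation λ²/(λ² + λ²/4 + σ²); with a
single submodule per module the g term is omitted and the flat
within-module correlation is λ²/(λ² + σ²). The submodule loading is
fixed at λ/2 so the second level is detectable only after first-level
splitting. Defaults (λ = 2, σ = 1, 100 tumor + 3 healthy samples, 20%
DE at ±2 log₂ units, 5% missing completely at random, 23 chromosomes)
emulate the shape of a consortium-scale breast-tumor proteomics study at desk scale.
Missingness is MCAR applied after signal generation — real
mass-spectrometry missingness is abundance-dependent, which is *not*
emulated, so passing QC tests here says nothing about MNAR behaviour.
Similarly not emulated: peptide-level artifacts, batch effects, isobaric
channel structure, scale-free degree topology, and realistic gene
symbols. Recovery results on synthetics demonstrate the machinery, not
field performance.

Study sizes in the tests and acceptance script (120–250 proteins, 100
tumor samples, 10⁵ permutations, 5 generator seeds) were chosen as the
smallest sizes at which the statistical properties under test are
well-resolved.

## Numerical choices

- `chi2_crit = 7.815`, `min_points = 8`: the standard adaptive-partition
  stopping rule.
- Null tail fit over the top 5% of pooled null MI values; empirical
  survival preferred above a 50-exceedance floor.
- Seeds: every stochastic step (generation, jitter tie-breaks, null
  permutations) takes an explicit seed; `run_pipeline()` fans a master
  seed out as seed+1 (simulation), seed+2 (rank transform), seed+3
  (null calibration) so stages can be rerun in isolation. RNG state is
  always restored, so library calls never perturb user-level draws.
- Degenerate inputs: constant rows rank via seeded random permutation
  (with warning); zero posterior variance in the moderated t yields
  p = 0 with a warning; an edgeless network is a partitioning error;
  empty enrichment tables propagate as empty matrices.
- lfc = 0 → sign +1; top-k ties kept; DPI requires strict inequality to
  remove an edge (an all-equal triangle survives).

## Interfaces

Everything is plain text: matrix/metadata/edge-list/partition TSV, GMT
collections, two-column chromosome maps, SIF export for network tools,
JSON for statistics and provenance. `run_pipeline()` orchestrates the
stages from a `pipeline_config()` (or YAML file), writes all outputs
plus a provenance record (config echo, seed, versions, input checksums)
into a run directory, and marks failures with a `FAILED` file naming the
stage. `compare_networks()` puts two edge lists side by side (overlap,
cis/trans, component sizes) — e.g. a protein network against an
externally supplied gene co-expression edge list.
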