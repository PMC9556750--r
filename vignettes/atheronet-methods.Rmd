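---
title: "Models and methods behind atheronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atheronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atheronet)
```

`atheronet` analyses patient-matched single-cell RNA-seq from the
atherosclerotic core (AC) and the proximally adjacent (PA) artery
segment. This vignette is the package's own account of the models it
fits, the parameters that matter, the numerical choices made where the
design was open, and — because every stage is benchmarked against a
synthetic generator with planted truth — what those benchmarks do and do
not demonstrate about real tissue data.

## 1. The count container and quality control

Counts live in a `count_matrix`: a sparse genes × cells UMI matrix with a
cell table (barcode, sample, patient, region ∈ {AC, PA}) and a gene table
(symbol, mitochondrial flag, default prefix `MT-`). QC removes cells by
three rules applied with *strict* inequalities — mitochondrial fraction
> 10% of raw UMIs, detected genes (UMI ≥ 1) < 200, detected genes
> 4000 — so cells sitting exactly on a boundary are retained. Each
removed cell is counted once under the first failing rule (mito → low →
high), which makes the report columns sum exactly to the removals.
Mitochondrial fractions are computed on raw UMIs before any
normalization, and "detected" means UMI ≥ 1 throughout the package; both
are the lowest-assumption readings and are stated here because other
toolchains differ.

Because AC tissue yields several times more cells than PA tissue,
unsupervised steps would otherwise be dominated by the core.
`downsample_equal()` draws an identical quota per sample (17,100 cells
over 6 samples = 2,850 each, at full scale); a sample below quota keeps
all of its cells with a warning and the achieved total is reported —
never silently re-allocated — so region balance stays auditable.

## 2. Partitioning, markers, and the doublet filter

Cells are partitioned by Louvain modularity optimization on a
k-nearest-neighbor graph built in PC space (top 20 PCs of
log1p(depth-normalized) counts). Graph partitioning was chosen over
embedding-space clustering because it is deterministic under a seed and
directly testable. `k_neighbors` acts as the resolution control:
at desk scale (a few hundred cells per type), k = 15 fragments types
along patient substructure while k = 20–30 recovers the planted types
with ARI 1.0; the default is 20. Partitions below 50 cells are dropped
(`drop_small_partitions()`) before marker work, as they are too small
for differential expression and are frequently doublet micro-clusters.

Markers follow two ubiquity rules, again with strict inequalities:
partition markers are genes expressed in > 80% of a partition's cells at
mean raw count > 2; *exclusion* markers (for doublet filtering) must be
expressed in > 90% of their own partition and < 10% of every other
partition. Since 10% < 90%, a gene can own at most one partition, so
exclusion sets are disjoint by construction. A cell expressing ≥ 2
exclusion markers belonging to partitions other than its own is flagged
as a putative doublet. One subtlety found during testing and now part of
the contract: exclusion sets are discovered on the *large* partitions
only, but *every* cell is screened. Cells in small dropped partitions
have no exclusion set of their own, so all their expressed exclusion
markers count as foreign — precisely the desired behavior, because small
partitions are where cross-type doublets accumulate, and counting their
markers as "own" would simultaneously destroy the rarity criterion for
their parent types.

Flags are validated by physics rather than statistics: a doublet carries
the summed transcriptome of two cells, so flagged cells must show
elevated total UMI. `validate_doublets_readcount()` reports the shift and
a one-sided rank-sum p-value; validation passes only if the flagged mean
exceeds the unflagged mean.

## 3. Normalized-effect differential expression

Expression is depth-normalized to the median library size,
log1p-transformed, and standardized per gene to zero mean and unit
variance. On that scale the coefficient of a linear model is directly an
effect size — the *normalized effect* (NE). The model per gene is

```
standardized expression ~ region + patient
```

with PA coded 1, so NE > 0 means higher in PA and NE < 0 higher in AC.
Patient identity enters as a factor covariate and absorbs patient-level
shifts exactly (a property test adds per-patient constants and verifies
the contrast coefficient is unchanged to 1e-6). Confounded designs —
every patient observed in one region only — are rejected with a
diagnostic rather than silently fitted. P-values are two-sided t-tests
on the contrast coefficient; q-values are step-up Benjamini–Hochberg
across tested genes (genes expressed in ≥ 1% of cells; zero-variance
genes are reported with NE 0, p 1). Downstream selection uses
q < 0.05 ∧ (NE > 0.5 ∨ NE < −0.5).

One consequence of unit-variance standardization is worth stating
plainly: a two-group mean difference on a unit-variance response cannot
exceed 2, so NE is bounded. Tools that normalize without the
unit-variance step can report much larger nominal effect values for the
same biology; `atheronet`'s NEs are comparable across genes precisely
because of the standardization, at the cost of a compressed scale.

## 4. Enrichment

`preranked_gsea()` implements the classic weighted Kolmogorov–Smirnov
running sum on an NE-ranked list: hits increment by |score|^weight
(weight 1 by default; at weight 0 the ES is invariant to positive score
rescaling), misses decrement uniformly, ES is the extremum, and the
leading edge is the set members at or before it (at or after for
negative ES). Only a single ranked list exists in this design, so the
null is gene-label permutation (n_perm = 1000 by default); NES divides
ES by the mean |null ES| of matching sign and FDR q follows the
sign-matched pooled-null rule. The ES computation is cross-checked in
the tests against an independent implementation and against
hand-enumerated running sums. Hallmark/ontology collections are
user-supplied GMT files; bundled tests use synthetic sets only.

Overlap questions (DE genes × module genes, hallmark leading edge ×
module) use the one-tailed Fisher exact test, computed as the
upper-tail hypergeometric probability P(X ≥ overlap) and verified by
full enumeration at small sizes.

## 5. The shrinkage partial-correlation network

The network stage is the package's core. For genes *i*, *j* the partial
correlation conditions on all remaining genes: with Ω the
(pseudo-)inverse of the correlation matrix,
pcor_ij = −Ω_ij / √(Ω_ii Ω_jj). With more genes than cells the sample
correlation matrix is singular, so it is shrunk toward the identity,
R\* = (1−λ)R + λI, with the analytic variance-minimizing intensity
λ = Σ var(r_ij) / Σ r_ij² (clamped to [0,1]) before Moore–Penrose
pseudo-inversion. At λ = 0 the estimate reduces to plain inverse
correlation, which the tests verify against explicit `solve()` to 1e-8;
a chain simulation (X → Y → Z) verifies that conditioning removes the
indirect X–Z correlation that plain correlation retains.

Edge significance: the upper triangle is linearized, each pcor mapped to
z = atanh(pcor)·√κ with effective sample size κ = n − (p−2) − 3 (floored
at 3). Because shrinkage deflates the null spread, the null standard
deviation is fitted to the central 90% of the z distribution (divided by
the matching truncated-normal factor), giving empirical-null tail-area
FDRs; a plain BH mode is available behind a flag and both modes agree on
the top-ranked edges. Edges are ranked by FDR, then |pcor|, with
lexicographic gene-pair tie-breaks, and the top-k ranked edges are
retained *even where FDR exceeds 0.05* — the deliberately relaxed regime
appropriate when modules are built from weighted edges. The default
top_k is 20,000, the genome-scale figure; at desk scale (300 genes =
44,850 pairs) the package's own scaling rule is top_k ≈ 2,000, roughly
the same top few percent of pairs.

Modules come from Louvain clustering of the retained-edge graph. Louvain
treats edge weights as affinities (stronger = more tightly connected),
so the default weights are |pcor|. A "reciprocal" mode (1/|pcor|) is
kept behind a flag because distance-flavored weighting is sometimes
used in this context; it inverts the usual modularity semantics and is
not the default. Node strength — Σ|pcor| over retained incident edges —
is the connectivity score used for driver ranking.

## 6. Key-driver subnetworks

Modules enriched in significant DE genes (one-tailed Fisher p < 0.05
over the network universe) move forward. Driver subnetworks keep the
top 15% of module genes by strength (computed on the module's induced
subgraph by default; a global-scope flag exists) together with all the
module's DE genes; a node is a *key driver* when q < 0.05, strength
> 0.3 (strict), and NE > 0.5 or < −0.5 (strict). The 0.3 cutoff is
interpreted as node strength, consistent with ranking genes by
connectivity; a per-edge interpretation would make the top-15% step
redundant. Hallmark specificity means exactly one module passes p < 0.05
for that hallmark's DE leading edge.

## 7. Subpopulations

Within a cell type, cells are re-clustered on the genes of the selected
modules: raw counts are binarized at UMI ≥ 2 (raw, never normalized —
binarization is deliberately insensitive to depth normalization), and
both axes are clustered by complete linkage under the binary distance
d = discordant / (discordant + both-on), which excludes joint absences;
an all-off pair is defined as distance 0 with a warning. Subpopulations
are nested cuts of the cell dendrogram (`cutree` at configured k values;
nesting holds by construction), and no k is hard-coded — the original
analysis shows different subpopulation counts per cell type. Each
subpopulation's AC fraction (AC cells / total) then serves as a
continuous axis of disease state: every gene's standardized expression
is regressed on its cell's subpopulation AC fraction and the
coefficients rank genes for ontology enrichment. With exactly two
subpopulations at fractions 0 and 1 the coefficient equals the
difference of subpopulation means, which the tests verify in closed
form.

## 8. The synthetic generator: what it emulates and what it does not

`generate_cells()` draws, per cell, a latent multivariate normal with a
*planted precision matrix*, maps each margin through its normal CDF to a
uniform and then to a negative binomial quantile. The monotone copula
transform preserves the partial-correlation structure the network stage
must recover while producing honest integer counts. Around this core:

* **Study design.** Defaults mirror a 3-patient paired design with the
  core/adjacent imbalance, linearly scaled to desk size: 1,300 AC and
  500 PA cells per patient (one tenth of the full-scale ~13k/~5k) over a
  300-gene roster. These sizes are the package's choice of benchmark
  scale; all are configurable.
* **Cell types.** Each type owns 3 exclusive high-expression marker
  genes (mirroring "3 known markers per type") plus 10 moderately
  elevated program genes, giving partitions structure beyond the markers.
* **Planted modules.** Module precision blocks are wired as a ring plus
  random chords (or a hub-and-spokes star) with entry magnitudes drawn
  from the configured pcor range and random signs. Uniform fully
  connected blocks cannot carry pcor ≈ 0.3 at size 20 (positive
  definiteness caps equicorrelated blocks near 1/(m−1)), and a bare
  chain is split by modularity optimization; ring-plus-chords is the
  sparse topology that is both plantable and recoverable. A star with
  s spokes requires Σ pcor² < 1, i.e. |pcor| < 1/√s — hub benchmarks
  plant 0.29 for 10 spokes, the largest feasible round value. If a draw
  still grazes singularity, a small ridge restores a minimum eigenvalue
  of 0.05 and the *realized* (slightly shrunken) edge values are recorded
  in the truth tables, so tests always compare against what was actually
  planted.
* **Planted DE.** Effects are specified on the normalized scale and
  applied as a centered latent shift s = δ/√(1 − δ²/4), the inverse of
  the unit-variance standardization algebra for a balanced two-group
  design, so the fitted NE recovers δ directly (hence |δ| < 2).
  Quantization attenuates effects planted on near-zero-count genes, so
  recovery benchmarks pin the DE gene's baseline mean (the `mean` column
  of `de_spec`) at a moderately expressed level, as showcased DE genes
  in real data are.
* **Batch structure.** Patient factors are gene-wise log-normal
  multiplicative effects on the NB mean, shared by both regions of a
  patient (sd 0.15 on the log scale), the structure the patient
  covariate is meant to absorb; cells get a log-normal size factor
  (sd 0.3) so depth normalization has work to do.
* **Doublets.** Spiked doublets are the element-wise sum of two cells of
  different types *from the same sample*, appended (not substituted) so
  singlet truth stays intact for recall computation.

Not emulated: ambient RNA, empty droplets, UMI saturation, per-cell-type
library-size distributions (the source data does not constrain them), or
read-level effects. Passing the planted-truth benchmarks therefore
demonstrates correctness of the estimators and thresholds under the
stated generative model — it does not certify performance under ambient
contamination or heavy batch nonlinearity, which real tissue can show.

## 9. Numerical choices and benchmark sizes

Determinism: every stochastic step (generation, downsampling, Louvain,
GSEA permutations) takes an explicit seed; identical configurations give
bit-identical output. Tie-breaks are documented where they matter: edge
ranking breaks FDR/|pcor| ties lexicographically by gene pair;
hierarchical merges follow `stats::hclust` order, deterministic given
input order. Degenerate inputs have defined behavior: zero-total cells
are removed under the low-genes rule with a warning; constant genes are
excluded before partial correlations; empty edge sets give empty module
sets; an empty reference table labels everything "unassigned".

The test suite and acceptance script run the pipeline at fixed
desk-scale sizes chosen to make recovery checks statistically meaningful
while keeping the default run fast: network recovery at 300 genes ×
2,000 cells over five replicates (module ARI and top-edge precision
reported as means over replicates — individual stochastic replicates of
any estimator fluctuate, and the mean is the quantity the benchmark
pins); DE calibration over ~1,100 null genes and effect recovery over
fifty replicates at 500 cells/region (mean recovery ≈ 0.98 of the
planted effect, sign correct in every replicate); the doublet filter on
the full default design (~5,700 cells) with 5% spiked doublets; and
fifty hub-driver replicates. `scripts/acceptance.R` re-derives all of
these from scratch at any seed.

## 10. Known limitations

* The linear model on standardized expression is a deliberate
  simplification; it makes "coefficient = effect size" exact but does
  not model count noise explicitly, and its p-values are calibrated
  empirically (type-I ≈ 0.05 in the null benchmark) rather than exactly.
* Louvain module boundaries on weakly connected background genes are
  seed-stable but not canonical; only planted-module recovery is
  guaranteed by the benchmarks.
* The marker-exclusion doublet filter needs partitions clean enough to
  support exclusion sets; heavily intermixed types (or doublet rates far
  above ~10%) erode the rarity criterion.
* Merging partitions that map to the same cell type across resolutions
  is left to an explicit user-supplied mapping; no automatic merge rule
  is imposed.
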