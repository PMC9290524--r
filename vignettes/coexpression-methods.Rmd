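---
title: "Coexpression modules and fungal abundance from field root transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression modules and fungal abundance from field root transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizomod)
```

# Scope

`rhizomod` implements an analysis chain for bulk root transcriptomes sampled
across heterogeneous field environments, of the kind used to dissect plant
nutrient-foraging strategies (mycorrhiza formation, phosphate-starvation
response, root development) from maize roots naturally colonized by
arbuscular-mycorrhizal (AM) fungi:

1. expression preprocessing (TPM, mean-TPM filter, log2);
2. weighted gene coexpression network analysis (WGCNA-style): soft threshold
   by scale-free fit, topological overlap, average-linkage clustering, module
   eigengenes and kME connectivity, eigengene-based merging;
3. module decomposition (k-means under correlation distance, PCA of member
   genes) and GO term enrichment (one-sided Fisher, Benjamini–Hochberg);
4. seeded-module extraction from a curated marker-gene list;
5. module–environment statistics (collinearity pruning, min–max
   standardization, multiple regression, correlation-matrix PCA biplots,
   gene–eigengene cross-correlation);
6. quantification of relative AM fungal abundance from rRNA reads embedded in
   mRNA-seq data, with Bray–Curtis/NMDS ordination;
7. a synthetic-data generator with planted ground truth that exercises every
   stage.

Everything upstream of the count matrix (mapping, counting) and of the rRNA
reference set (assembly, OTU curation) is out of scope.

# Expression preprocessing

Counts are converted to transcripts per kilobase million,
$\mathrm{TPM}_{gs} = 10^6 (c_{gs}/L_g) / \sum_g (c_{gs}/L_g)$, using the
transcript lengths supplied with the counts file; each sample column then
sums to $10^6$. Genes are retained when their arithmetic mean TPM across all
samples is at least the threshold (default 5, boundary inclusive), and values
are transformed as $\log_2(\mathrm{TPM} + 1)$. The pseudo-count of 1 is the
dominant convention for keeping zeros finite and is exposed as a parameter;
results are insensitive to it for the well-expressed genes that pass the
mean-TPM filter. Samples with all-zero counts cannot be normalized; they are
emitted as zero columns and flagged rather than silently dropped.

# Network construction

The network is **unsigned** with Pearson correlation:
$a_{ij} = |r_{ij}|^\beta$. Unsigned adjacency, Pearson correlation and
unsigned topological overlap are the canonical defaults of one-step WGCNA
construction; signed variants are exposed as options. The topological overlap
is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{j \neq i} a_{ij},$$

with $\mathrm{TOM}_{ii} = 1$ and zero-denominator cells defined as 0. Genes
are clustered by average linkage on $1 - \mathrm{TOM}$.

**Soft threshold.** For each candidate power, connectivities are binned into
10 equal-width bins and $\log_{10}$ bin frequency is regressed on
$\log_{10}$ mean bin connectivity; the signed fit index is
$-\mathrm{sign}(\mathrm{slope}) \cdot R^2$. The chosen power is the smallest
one whose fit reaches the target (default 0.9). When no power reaches the
target — which happens routinely when the fit curve plateaus just below it —
the scan falls back to the conventional sample-size-based default for
unsigned networks (6 for ≥ 40 samples, 7 for ≥ 30, 8 for ≥ 20, 9 below)
rather than taking the argmax of the plateau: on data with several hundred
unstructured genes the plateau's maximum drifts toward very high powers,
where adjacency decays so fast that modules disintegrate.

**Module cutting and refinement.** The dendrogram is cut at a static height
(default 0.995 on the $1-\mathrm{TOM}$ scale); branches with at least
`min_module_size` (default 30) leaves become modules, named by size rank from
the standard color list. A static cut is deterministic and easy to reason
about, but on its own it is fragile against the soft power: at low powers the
permissive cut admits weakly chance-correlated background genes, at high
powers genuinely connected low-kME members fall off the branch. Detection
therefore runs a kME refinement pass (up to two iterations): every gene is
reassigned to the module whose eigengene it matches best, provided
$|kME| \ge 0.5$, modules falling under the minimum size dissolve, and
eigengenes are recomputed. The 0.5 membership threshold is the usual
moderate-correlation cutoff — the same criterion used for seeded-module
extraction — and sits a null-distribution's width (5 s.d. at $n = 100$
samples) above chance correlation. Refinement can be disabled
(`refine_min_kme = NULL`) to obtain the raw static cut.

**Eigengenes.** A module eigengene is the first principal component's sample
scores computed from the row-z-scored member expression, rescaled to unit
variance and sign-oriented so that the mean correlation with member genes is
positive. Because rows are centered, eigengenes have exactly zero mean.
Modules whose eigengenes are closer than a dissimilarity threshold
($1 - r <$ height) are merged greedily, closest pair first, recomputing the
merged eigengene after every merge; the pipeline applies a construction
merge at 0.2 and a final merge at 0.3, mirroring the two-stage practice of
building the network and then consolidating similar modules.

# Module structure and enrichment

Submodules are found with `stats::kmeans` on row-z-scored profiles (squared
Euclidean distance on z-scores is monotone in centered correlation distance
$1-r$), best of 20 restarts, deterministic under the seed. Centered rather
than uncentered correlation is used because centered is the default of the
clustering tools in this field; uncentered can be obtained by skipping the
centering externally. Module PCA treats genes as observations of their
z-scored profiles without further column centering, so a module of identical
profiles is rank 1 — the configuration in which all variance lies on PC1.

GO enrichment uses the one-sided (greater) Fisher exact test per term —
enrichment, not depletion, is the question of interest — with
Benjamini–Hochberg adjustment across terms; annotations are used exactly as
given (no propagation up the GO graph). Conventional FDR cutoffs are 0.01
for modules and 0.05 for submodules.

# Seeded modules

Seed genes are selected from an explicit candidate list (in practice a
curated set of nutrient-assimilation genes) by Pearson correlation with an
environmental factor, two-sided $t$ p-value below $\alpha$ (default 0.05) and
the requested sign (default negative, the low-nitrate response direction).
The seed PC1 scores are computed exactly like a module eigengene; the seeded
module is then every filtered gene with $|r| > 0.5$ (strictly) against those
scores. The $|r|$ criterion is primary; the associated p-value is reported
but not enforced, because the p-value that accompanies $|r| = 0.5$ depends
entirely on the sample count. Overlap with an existing module set is counted
per module, and the seeded eigengene is correlated against every existing
eigengene.

# Module–environment statistics

Factor collinearity is pruned before regression: factor pairs are scanned in
input column order and whenever two retained factors correlate with
$|r| \ge 0.9$ (pairwise-complete), the later-listed one is dropped — the
order-based rule is deterministic and auditable. Response and factors are
standardized to $[-50, +50]$ by the affine map
$v' = -50 + 100(v - \min)/(\max - \min)$, which leaves correlation structure
untouched, and fitted by ordinary least squares on complete cases with
per-coefficient $t$-tests (stars at 0.05/0.01/0.001), $R^2$ and the overall
$F$-test. Correlations themselves are pairwise-complete; the differing
missing-data policies (pairwise for correlation tables, complete-case for
regression) follow common practice and are both recorded in the outputs.
The module-by-factor correlation matrix feeds a PCA biplot with modules as
observations; columns are centered but not rescaled since all cells already
live on the common $r$ scale.

# Dual-RNA fungal quantification

Fungal LSU OTU references carry conserved terminal consensus sequences;
exact terminal matches are trimmed before assignment so reads map only to
the variable core. Reads are assigned by a bundled ungapped matcher: exact
15-mer seeds on both strands propose (reference, diagonal) candidates, each
candidate is scored as the full ungapped alignment at that diagonal (clipped
at reference ends), and the best hit is accepted at ≥ 95% identity over
≥ 75 aligned bases. Ties go to the higher identity, then the longer
alignment, then the lexicographically smallest reference id. Seeds are
placed every 4 bases plus the final window; with 75 bp reads and ~1%
substitution error the probability that no clean seed survives is
negligible, which the assignment-rate benchmark confirms. An E-value
criterion is not implemented — identity and length dominate acceptance at
this read length — and the matcher is pluggable so an external aligner can
substitute.

Assigned counts are divided by the post-trim reference length (counts per
nt), fungal totals are standardized per $10^5$ plant rRNA reads and
$\log_{10}$-transformed into the abundance index
$\log_{10}(10^5 \sum_{otu} c_{otu}/L_{otu} \,/\, (c_{plant}/L_{plant}))$.
Log base 10 is a deliberate choice; samples with zero plant or zero fungal
counts are flagged missing rather than pseudo-counted, so the index is only
reported where it is defined. Protocol bias between two library types is
assessed as the Pearson correlation of the log indices over shared samples.

Community structure uses Bray–Curtis dissimilarity
($\sum|u_i - v_i| / \sum(u_i + v_i)$, via `vegan::vegdist`) and an
in-package NMDS: Kruskal stress-1 minimized by alternating isotonic
regression (primary tie handling, via `stats::isoreg`) with Guttman
majorization updates, guarded by step halving so the recorded stress trace
is monotone non-increasing. The first start is the classical-scaling
configuration — which solves the embeddable case immediately — and the
remaining starts are random; the best final stress wins, deterministically
under the seed.

# Synthetic data: what it emulates and what it does not

The generator plants known structure so that every downstream stage has a
ground truth:

* **Factors.** Each soil/plant factor is drawn independently per sample,
  uniformly or log-uniformly within its range. Defaults use two
  nutrient-style gradients spanning the ranges observed across field sites
  (NO3-N 10.5–212 mg kg⁻¹, Bray II-P 5.3–494 mg P kg⁻¹, both log-uniform, as
  soil nutrient concentrations are right-skewed) plus uniform auxiliary
  factors, one per module.
* **Expression.** Module eigengenes are standardized linear responses to the
  standardized factors plus Gaussian noise (`noise_sd`, default 0.3 — strong
  but not dominant environmental control). A member gene with planted
  connectivity kME has latent profile
  $kME \cdot E_m + \sqrt{1 - kME^2}\,\varepsilon$; planted kME is uniform in
  [0.6, 0.95], background genes are pure noise. Latent profiles map to
  expected TPM through $\exp(\cdot)$ rescaled so every gene's mean TPM is 50
  (comfortably above the filter threshold of 5), and counts are Poisson
  draws of each gene's share of a $10^6$-read library; negative-binomial
  overdispersion is exposed as an option. Defaults: 5 modules × 100 genes,
  500 background genes, 100 samples.
* **rRNA reads.** One synthetic plant LSU reference (3000 nt) and a handful
  of OTU references (610 nt cores flanked by the shared consensus
  sequences). Reads (75 bp single-end, matching the study design the
  package targets) are drawn from the references proportionally to planted
  abundances, with uniform positions, random strand and substitution errors
  at 1% by default; read names encode the true source. The per-sample
  fungal-to-plant abundance ratio follows a log-uniform gradient
  (defaults $10^{-3}$–$10^{-1}$), emulating the wide range of colonization
  across field sites.

The generator does **not** emulate: correlated factor gradients across
sites, genotype or site block structure, mappable mRNA reads, overdispersion
beyond the NB option, GO biology (annotations are random apart from one
enriched term planted per module), chimeric or gapped rRNA reads, or
compositional OTU biases between library protocols. Passing the benchmarks
therefore demonstrates that the algorithms recover the structure they are
specified to recover — not that field data meet these assumptions.

# Benchmarks and problem sizes

The test suite and the acceptance script (`scripts/acceptance.R`) recompute,
from scratch, per run:

* module recovery across 20 simulated datasets at the default conditions
  (adjusted Rand index against planted labels; correlation between planted
  and estimated kME);
* exact-oracle agreement for TOM (brute-force triple loop), Fisher
  enrichment (hypergeometric tail sums; complete enumeration of small
  universes plus a random sweep up to universe size 100), OLS (normal
  equations) and Bray–Curtis (elementwise evaluation);
* seeded-module recovery at 200 samples; regression recovery of planted
  standardized effects at 200 samples over 20 replicates;
* read assignment rate/accuracy and abundance-index recovery over 50
  samples at the default depth (2000–4000 rRNA reads per sample); protocol
  concordance with identical abundances at 20 samples × 30 000 reads and
  fungal fractions 0.01–0.3 — sequencing runs in the emulated comparison
  are orders of magnitude deeper than desk-scale simulation, so concordance
  is assessed at a depth where counting noise is small relative to the
  abundance gradient;
* NMDS behavior on exactly embeddable inputs and monotonicity of the stress
  trace; byte-level reproducibility of a full pipeline rerun.

These problem sizes keep a full run in a few minutes on a single CPU while
leaving each statistic enough data to be stable.

# Numerical choices and degenerate inputs

* Constant (zero-variance) genes are rejected with named errors wherever a
  correlation would be undefined (adjacency, soft-threshold scan, kME).
* Degenerate connectivity binning (constant k) yields a missing fit value
  for that power instead of an error; a scan where every power is missing
  falls back to the first power.
* `min == max` factor ranges are allowed and produce constant columns;
  `min > max` is a configuration error.
* kME percentile ranks use `ceiling(p/100 · size)` with kME ties broken by
  gene id; reference genes with zero TPM yield missing ratios for those
  samples.
* The eigengene sign rule (positive mean member correlation) makes results
  invariant to negating member genes.
* TOM cells with zero denominator are defined as 0; values are clipped into
  [0, 1] against floating-point overshoot.
* NMDS accepts an update only if stress does not increase (up to 10 step
  halvings), guaranteeing the monotone trace at the cost of, rarely,
  stopping at a local optimum — mitigated by multiple starts.
* All stochastic stages derive their streams from one master seed with
  stage-specific offsets, so a single integer reproduces a whole run,
  including byte-identical pipeline outputs.

# Known limitations

* The static-cut-plus-refinement module detector is simpler than the dynamic
  hybrid tree cut; very close or nested modules that the hybrid algorithm
  separates may merge or trade members here.
* The bundled read matcher is ungapped; indel-rich references require the
  external-aligner adapter.
* Sample sizes below ~30 leave kME and seed-selection p-values underpowered;
  the defaults assume the O(100)-sample regime the package targets.
* The pipeline is in-memory and aimed at filtered gene sets of up to a few
  thousand genes; block-wise computation for much larger matrices is out of
  scope.
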