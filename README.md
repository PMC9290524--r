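# rhizomod

Gene coexpression modules and mycorrhizal abundance from root transcriptomes.

## The problem

Plants forage for nitrogen and phosphorus through several strategies at
once — arbuscular-mycorrhizal (AM) symbiosis, phosphate-starvation responses,
root system development — and field transcriptomes of roots sampled across
contrasting soils are a way to ask how these programs are coordinated. The
standard analysis is weighted gene coexpression network analysis (WGCNA):
genes with correlated expression across samples form modules, each module is
summarized by an *eigengene* (PC1 sample scores of its standardized member
expression), and eigengenes are related to soil and plant factors by
correlation and regression. Because the roots are naturally colonized by AM
fungi, the same mRNA-seq libraries also contain a trace of rRNA reads from
both partners, which can be turned into a relative measure of fungal biomass.

`rhizomod` packages that whole chain for R users:

* **Expression**: TPM normalization (`counts_to_tpm`), mean-TPM ≥ 5 filter,
  log2 transform.
* **Network**: soft-threshold selection by scale-free topology fit
  (`pick_soft_threshold`), unsigned adjacency `|r|^β`, topological overlap
  (`topological_overlap`), average-linkage clustering, static tree cut with
  kME refinement, eigengenes (`compute_eigengene`), eigengene-based module
  merging at heights 0.2 and 0.3, and kME connectivity
  (`module_connectivity`) — all behind the one-call `detect_modules()`.
* **Module structure**: k-means submodules under correlation distance,
  module PCA, GO enrichment by one-sided Fisher test with BH correction.
* **Seeded modules**: select marker genes correlated with a factor
  (`select_seed_genes`), score samples by the seeds' PC1, and extract all
  genes with |r| > 0.5 against those scores (`extract_seeded_module`), with
  overlap accounting against an existing module set.
* **Module–environment**: collinearity pruning (|r| ≥ 0.9 rule), [−50, +50]
  min–max standardization, multiple linear regression of eigengenes on
  factors, correlation-matrix PCA biplots, gene–eigengene cross-correlation
  distributions.
* **Dual-RNA quantification**: consensus trimming of fungal OTU references,
  k-mer seeded ungapped read assignment (≥ 95% identity over ≥ 75 bp),
  per-nt length normalization, the fungal abundance index (reads per 10⁵
  plant rRNA reads, log10), protocol-bias correlation, Bray–Curtis
  dissimilarity and NMDS.
* **Synthetic data**: `sim_config()` / `simulate_dataset()` plant modules
  driven by latent soil gradients, background genes, and plant/fungal rRNA
  read mixtures with known abundances, so every stage can be benchmarked
  against ground truth.

See the methods vignette (`vignettes/coexpression-methods.Rmd`) for the
models, defaults and design decisions.

## Worked example

Simulate a field-style dataset (100 samples, 5 planted modules of 100 genes
on nutrient gradients, 500 background genes), detect modules, and relate
them to the environment:

```r
library(rhizomod)

cfg <- sim_config(seed = 42)
ds  <- simulate_dataset(cfg, with_rrna = FALSE)

expr <- log_transform(filter_by_mean_tpm(counts_to_tpm(ds$counts)))
net  <- detect_modules(expr)
net$scan
#> soft-threshold scan: chosen power 5 (fit 0.912, target 0.90)
net$modules
#> module_set: 5 modules over 1000 genes; 508 unassigned
#>      blue     brown     green turquoise    yellow
#>        99        99        99        99        96
```

Five modules of ~99 genes are recovered; the 508 unassigned genes are almost
exactly the 500 planted background genes (adjusted Rand index vs truth:
0.977). Each eigengene tracks its planted driving factor:

```r
round(module_factor_correlations(net$modules$eigengenes, ds$factors)$r, 2)
#>           NO3_N BrayII_P factor_3 factor_4 factor_5
#> blue      -0.07    -0.23     0.91    -0.21    -0.07
#> brown      0.92    -0.26    -0.01    -0.15    -0.15
#> green     -0.14    -0.08    -0.06    -0.12     0.93
#> turquoise -0.15     0.01    -0.19     0.92    -0.10
#> yellow    -0.22     0.92    -0.16     0.07    -0.03
```

The brown module is the nitrate-responsive one; its regression on the
(min–max standardized) factors recovers that driver:

```r
pruned <- drop_collinear_factors(ds$factors)
fit_module_regression(net$modules$eigengenes["brown", ], pruned$factors)
#> module regression: n = 100, R^2 = 0.912, overall F p = 6.66e-48
#>        factor coefficient     t        p stars
#> 1 (Intercept)      7.4803  6.91 5.72e-10   ***
#> 2       NO3_N      0.6452 29.38 3.65e-49   ***
#> 3    BrayII_P     -0.1219 -4.91 3.81e-06   ***
#> ...
```

The NO3-N coefficient dominates (0.65, p ≈ 4e-49) and R² ≈ 0.91: the module's
expression is explained by the factor that generated it. The same dataset
(with `with_rrna = TRUE`) carries simulated rRNA reads; `assign_reads()`,
`length_normalize_counts()` and `fungal_abundance_index()` turn them into a
per-sample log fungal-abundance index, and `bray_curtis()` + `nmds()`
ordinate the OTU communities.

A full run — preprocessing, network, submodules, enrichment, seeded module,
environment statistics, dual-RNA quantification, with every artifact and a
JSON manifest on disk — is one call:

```r
run_pipeline(pipeline_config(out_dir = "run1", seeded_factor = "NO3_N",
                             seed = 1), dataset = simulate_dataset(cfg))
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/scripts/rhizomod.R simulate --seed 1 --out demo_data
Rscript inst/scripts/rhizomod.R run-all --data demo_data --out demo_run --seeded-factor NO3_N
```

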