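# stageSigNet

Discovery of stage-discriminative gene signatures and network
"gatekeepers" in an ordered eight-stage carcinogenesis expression
series (normal → metaplasia → dysplasia grades → carcinoma in situ →
invasive squamous-cell carcinoma).

For computational biologists who have (i) a genes × samples expression
matrix with ordered histological stage labels, (ii) a protein–protein
interaction edge list, and optionally (iii) a GMT gene-set collection,
the package provides:

* **Differential expression** of each stage against the pooled normal
  control: per-gene pooled-variance t with optional empirical-Bayes
  moderation (variances squeezed to
  s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), prior fitted by method of
  moments on log variances), Benjamini–Hochberg adjustment, a signed
  fold-change filter (|FC| > 1.5, adjusted p < 0.05), and a union
  merge across contrasts with provenance.
* **Gatekeeper detection** on the induced PPI subnetwork via
  clustering centrality C_i = 2E_i / (k_i(k_i − 1)): a gatekeeper has
  C_i = 1 with degree ≥ 2 — all of its (few) neighbors are pairwise
  connected hubs. Equality is tested in integer arithmetic
  (2E_i = k_i(k_i − 1)), plus edge-list cleaning, neighborhood edge
  closures and largest-component extraction.
* **Signature reduction**: a ridge-penalized softmax multinomial stage
  classifier whose class × gene coefficients are jointly standardized;
  genes with max-over-classes |z| > 0.78 are kept, the model is
  retrained and the rule applied a second time. Reported alongside a
  **random-signature null**: classifiers trained on random gene sets
  of the same size, scored by the macro-averaged Jaccard index
  TP/(TP + FP + FN).
* **Fisher exact over/under-representation** of a gene list against a
  GMT collection with BH-FDR across the tested sets.
* A **seeded synthetic-data module** (expression with planted monotone
  stage signatures; scale-free-ish interactomes with planted hubs and
  gatekeepers repaired to be the *only* centrality-1 nodes) so the
  whole pipeline runs and is tested fully offline.

## Worked example

```r
library(stageSigNet)

cfg <- pipelineConfig(
  outdir       = "demo_run",
  sim_network  = networkSimConfig(n_nodes = 500L),
  n_null_sets  = 100L,
  seed         = 1L)
manifest <- runPipeline(cfg)
```

```
[stageSigNet] simulating expression and interactome
[stageSigNet] fitting stage-versus-control contrasts
[stageSigNet] 18 genes pass the filter in >= 1 contrast
[stageSigNet] inducing subnetwork and scoring clustering centrality
[stageSigNet] 3 gatekeepers; big component has 11 nodes
[stageSigNet] two-round signature reduction
[stageSigNet] signature of 15 genes; accuracy 0.944, macro Jaccard 0.898
[stageSigNet] random-signature null (100 sets)
[stageSigNet] wrote demo_run/manifest.json
```

What the numbers mean: the synthetic series (107 samples, 8 stages,
2000 genes, 15 planted signature genes) yields 18 merged
differentially expressed genes; the three planted gatekeepers are
recovered from the induced subnetwork; the 15-gene signature (capped
by standardized-coefficient ranking; here it equals the planted set)
classifies 94.4% of the training samples into the correct stage, a
macro Jaccard of 0.898, while the best of 100 random 15-gene sets
reaches only

```r
manifest$scores$null_max
#> [1] 0.6267144
manifest$scores$empirical_p
#> [1] 0.00990099
```

so the signature separates cleanly from the random-set null — the
structure (though not the exact values) of the published
0.92-versus-0.29 contrast this pipeline re-implements. Per-stage
differential-expression tables, the centrality/gatekeeper tables, the
confusion matrix, the null distribution and a hash manifest are all
written under `demo_run/`; rerunning the same config reproduces
byte-identical hashes.

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch on
the synthetic world (simulation → differential expression → network
and gatekeepers → two-round reduction → evaluation → 100-set null →
enrichment against a toy GMT) and writes a JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.
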