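---
title: "Stage signatures and network gatekeepers: methods and design notes"
author: "stageSigNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage signatures and network gatekeepers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageSigNet)
```

# The problem

Squamous-cell lung carcinoma develops through an ordered series of
bronchial lesions: two histologically normal states (normo- and
hypo-fluorescent), metaplasia, three grades of dysplasia, carcinoma in
situ, and invasive carcinoma. Given a genes-by-samples expression
matrix over such a series, this package looks for two kinds of
stage-relevant genes:

* **Network gatekeepers** — genes that are differentially expressed
  somewhere along the series and occupy a characteristic position in
  the protein–protein interaction (PPI) network: few neighbors, all of
  which are interconnected hubs. Formally, a gatekeeper is a node whose
  clustering centrality
  $C_i = \frac{2E_i}{k_i(k_i - 1)}$
  equals exactly 1, where $k_i$ is the node's degree and $E_i$ the
  number of edges among its neighbors.
* **A compact classifier signature** — a small gene set whose
  multinomial (softmax) logistic model assigns samples to the correct
  stage, obtained by two rounds of training followed by
  standardized-coefficient thresholding.

Every step is exercisable offline through a seeded synthetic-data
module; nothing in the package downloads data.

# The pipeline, stage by stage

## Differential expression against a pooled control

The two normal stages are pooled as the control group and each
remaining stage is contrasted against it. Per gene, the statistic is a
two-sample pooled-variance t. By default the per-gene variances are
moderated: the sample variances $s^2_g$ (on $d_g$ degrees of freedom)
are assumed to follow a scaled inverse-chi-square prior with
hyperparameters $(d_0, s_0^2)$, fitted across genes by method of
moments on $\log s^2_g$ (log-F moments, with a Newton inversion of the
trigamma function), and each gene's variance is squeezed to
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$, with the t
referred to $d_0 + d_g$ degrees of freedom. Setting `moderated = FALSE`
(equivalently $d_0 = 0$) recovers the ordinary pooled t exactly. The
test suite cross-checks both the fitted prior and the full moderated t
against limma on identical inputs.

P-values are Benjamini–Hochberg adjusted within each contrast
(`bhAdjust()`, cross-checked against `p.adjust`). Genes pass a contrast
when the adjusted p is below `p_thresh` (0.05) **and** the signed
linear-scale fold change is strictly beyond `fc_thresh` (1.5). With
log2-scale input the signed fold change of a mean difference $d$ is
$2^d$ for $d \ge 0$ and $-2^{-d}$ otherwise, so down-regulation reads
as $< -1.5$. Lists are merged across contrasts as a deduplicated union
with per-gene provenance.

Two deliberate interpretation choices, both exposed as flags:

* the p filter applies to the **adjusted** p-value (the adjustment is
  computed immediately before filtering, so filtering the raw p would
  make the adjustment pointless); `use_adjusted = FALSE` switches to
  raw p;
* multiple probes per symbol are kept probe-level through the
  differential-expression step and collapsed only at the network
  boundary, by maximum $|t|$ across contrasts.

Note that a union of per-contrast BH-filtered lists does **not**
control the false-discovery rate of the union: with six contrasts at
FDR 0.05 each, the merged list's FDR can approach the sum. The
parameter-recovery test freezes Monte-Carlo-measured bounds (complete
sensitivity, union false positives bounded well above the naive 5%)
rather than pretending union control.

## Network cleaning, induction and gatekeepers

Edge lists are cleaned the way an interactome download is cleaned:
reversed duplicates collapse to one undirected edge, self-loops are
removed, and an optional taxon column filters cross-species rows; all
removals are counted in a report. The merged gene list induces a
subnetwork (absent genes are reported, not dropped silently; a flag
optionally expands the induction by first neighbors). Clustering
centrality is computed exactly — neighbor-edge counts come from
$\mathrm{diag}(A^3)/2$ on the sparse adjacency matrix and are integers
— and gatekeeper calls test $2E_i = k_i(k_i-1)$ in integer arithmetic,
so no floating-point tolerance is involved.

Degree-0 and degree-1 nodes have an undefined centrality
($k(k-1) = 0$); the package assigns $C = 0$ by convention and excludes
them from gatekeeper calls via `min_degree = 2`, since a gatekeeper
must bridge at least two interconnected neighbors. A clique such as
$K_3$ makes every node a "gatekeeper" by the bare definition; this
degenerate case is documented rather than special-cased.

## The classifier and the two-round reduction

The stage classifier is a true softmax multinomial (not one-vs-rest)
with an L2 ridge penalty on the non-intercept coefficients, minimized
by L-BFGS with an analytic gradient from an all-zero start — a
deterministic convex optimization, so identical inputs give identical
coefficients; the test suite cross-checks fitted probabilities against
glmnet's ridge multinomial. Regularization is necessary because the
intended data regime has far more genes than samples; the default
strength (`l2_strength = 1` on the summed likelihood) is deliberately
mild. Features are z-scored per gene before training — without a
common scale, thresholding coefficient magnitudes would be
meaningless; the evaluation protocol follows the original design of
training and evaluating on the same records (a cross-validated mode is
out of scope here because the method under study did not use one).

The reduction standardizes all class-by-feature coefficients jointly
(intercepts excluded) to $z = (\beta - \bar\beta)/\mathrm{sd}(\beta)$
with the population standard deviation, selects genes whose largest
$|z|$ over classes **strictly** exceeds 0.78, retrains on the
selection, and selects again. Both the strict inequality and the
max-over-classes aggregation are package decisions where the original
description is ambiguous; both are arguments of `selectFeatures()`.

### Why the 0.78 threshold cannot prune a Gaussian coefficient pool

This is the package's most important caveat. After joint
standardization the coefficient pool has unit standard deviation *by
construction*. If the pool is approximately normal — which is exactly
what happens when thousands of exchangeable noise genes dominate it,
as in the synthetic world — then any single entry exceeds 0.78 with
probability $\approx 0.435$, and the max over eight classes exceeds it
for $\approx 98\%$ of genes. A 0.78 threshold therefore only reduces a
model whose coefficient distribution is strongly heavy-tailed, as was
evidently the case on the real 41k-probe array data (where the rule
cut 41,067 genes to 800, i.e. 2%). Measured on the synthetic world,
the ridge fit's planted-to-background coefficient-magnitude ratio
saturates near 2.8 across effect sizes 1–5, noise levels 0.3–1 and
penalties 0.01–10, so no generator setting makes the pool heavy-tailed
enough. The corresponding acceptance check asserts the faithful
procedure and is expected to fail its precision half; the *ranking* of
standardized coefficients, by contrast, separates planted from
background genes almost perfectly, and `runPipeline()` caps the
reported signature at `signature_k` genes by that ranking (the
threshold-rule output is also written, as `signature_round2.tsv`).

## Evaluation and the random-signature null

`evaluateClassifier()` reports the confusion matrix (true classes in
rows), overall accuracy, and the per-class Jaccard index
$TP/(TP+FP+FN)$ with its macro average. Both accuracy and macro
Jaccard are always reported because the quantity called "Jaccard
index" in this literature is described as the proportion of correctly
classified cases (= accuracy) while the reported values track the
macro average better; the two coincide only in easy regimes.

The null control retrains the same classifier on `n_null_sets` random
gene sets of the signature's size and records each macro Jaccard. The
empirical p-value uses the add-one convention
$(1 + \#\{J_{null} \ge J_{obs}\})/(n_{sets}+1)$, which can never reach
zero. Two properties are tested: on planted-signal data the observed
signature beats the null maximum, and with permuted labels a fixed
signature falls inside the null's central 95% interval at the nominal
rate (the permutation check must use a signature chosen *before*
permutation — re-deriving it from permuted labels would smuggle
selection bias into the "observed" value).

## Enrichment

Gene-list enrichment is a two-sided Fisher exact test per gene set
(the sum of probabilities of all tables at most as likely as the
observed one), with direction assigned by comparing the observed
overlap with its hypergeometric expectation
$n_{input} \cdot K / N$, and BH adjustment across exactly the sets in
the supplied collection. Published FDR values from web tools are not
reproduction targets: they depend on the full pathway-database release
the tool queried. Harmonization is exact-match and case-sensitive; no
alias resolution is attempted.

# The synthetic world

`simulateStageExpression()` draws a genes-by-samples matrix on a
log2-like additive scale: baseline 8, i.i.d. Gaussian noise
(`noise_sd = 1`), eight ordered stages with per-stage sample counts
(13, 14, 15, 13, 13, 12, 13, 14) matching the bronchial-biopsy series
the package emulates (the first two stages pool as control; the
published per-stage counts sum to 107 even though the series is
described as 122 samples — the counts are config, the discrepancy is
not resolved here). Planted signature genes get a monotone ramp:
stage-$j$ mean $= 8 + j \cdot \texttt{effect\_size}$ ($j = 0..7$),
mimicking progressive dysregulation along an ordered carcinogenic
series; a step profile at a configurable stage is the alternative.
The default `effect_size = 1` (2-fold per stage step) is the smallest
value at which coefficient-ranking recovery of the planted signature
is robust across seeds; larger values would imply implausibly large
cumulative fold changes across the series.

`simulateInteractome()` builds a preferential-attachment background
(heavy-tailed, as PPI degree distributions are), plants a clique of
hubs topped up to a guaranteed minimum degree, attaches each
gatekeeper to 2–3 of those hubs and nothing else, and then repairs the
graph so that *only* planted gatekeepers have $C = 1$ at degree
$\ge 2$: every spurious such node receives one extra edge to a node
sharing none of its neighbors, which provably lowers both endpoints'
centralities below 1 without altering any third node's neighbor-edge
count, and cannot touch a planted gatekeeper. This makes the
gatekeeper round-trip (simulate, score, call) exact by construction,
and the test suite verifies exactness over 20 seeds.

What a green synthetic run does **not** establish: the generator has
no probe-level artifacts, no correlated co-expression among background
genes, no heavy-tailed coefficient pools (see above), and its
interactome couples network roles to planted genes so the induced
subnetwork is non-trivial — in real data the DGE list and the
interactome are independent inputs, the induced network is far larger,
and hub cliques do not survive induction unscathed (in the synthetic
induced network a hub whose induced neighbors happen to form a clique
is reported as a gatekeeper too; exact recovery is only guaranteed on
the full simulated network).

# Numerical choices and degenerate inputs

* Trigamma inversion: Newton iterations to relative $10^{-10}$; if the
  moment estimate of the prior spread is non-positive the prior df is
  infinite and all variances collapse to $s_0^2$.
* Optimizer: L-BFGS-B, `factr = 1e7`, up to 2000 iterations, zero
  start; the intercept gauge is fixed implicitly because the gradient
  is orthogonal to the all-ones intercept direction at the start.
* Gatekeeper equality is integer arithmetic; component ties break
  towards the component containing the lexicographically smallest node
  id; BH is step-up with explicit monotonicity enforcement.
* Degenerate inputs raise typed errors naming the offending field:
  zero-variance expression matrices, classes with fewer than two
  samples, empty selections after round 1, empty universes, conflicting
  probe annotations.
* All randomness flows from one root seed, split deterministically per
  pipeline stage (a small linear map kept below $2^{31}$), and every
  generator restores the caller's RNG state.

# Known limitations

* The published headline numbers (0.92 observed vs 0.29 null-max
  Jaccard, 41,067 to 800 to 15 genes, 26 gatekeepers) were produced on
  a specific deposited microarray series with unstated regularization
  and scaling choices; they are not desk-reproducible and the package
  does not claim them. The synthetic pipeline reproduces the
  *structure* of those results (a compact signature whose Jaccard far
  exceeds a random-set null; gatekeepers bridging hubs).
* The 0.78 reduction rule transfers poorly to well-conditioned
  coefficient pools (analysis above); use the ranking cap or tune the
  threshold to the pool at hand.
* The union of per-contrast BH-filtered gene lists does not control
  the union FDR.
* Enrichment assumes exact symbol matching and a user-supplied
  universe; no alias or ortholog handling.
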