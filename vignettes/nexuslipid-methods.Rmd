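---
title: "Methods and design notes for the nexuslipid pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the nexuslipid pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nexuslipid)
```

# Scope

`nexuslipid` implements a multi-stage analysis linking metabolic and
neurocognitive disease: bidirectional two-sample Mendelian randomization (MR)
with a sensitivity/qualification suite, trait-network community filtering,
instrument prioritization with positional gene mapping, hypergeometric
gene-set enrichment, pathway-restricted cross-validated classification with a
performance-weighted gene-scoring cascade, chemical–gene hub networks, and
moderated-t differential expression feeding a multi-parametric in vivo target
ranking. Because the real inputs (GWAS accessions, GEO cohorts, curated
chemical–gene databases, raw RNA-seq) are external and versioned, the package
ships seeded generators that produce every input with planted ground truth,
and the whole pipeline is validated against that truth.

# The MR engine

## Model and estimators

For each exposure–outcome pair, instruments are selected at genome-wide
significance ($P < 5\times10^{-8}$) and greedily LD-clumped ($r^2 < 0.001$
within a 1,000 kb window): candidates are ranked by ascending $P$ and a SNP is
kept iff its $r^2$ with every previously kept SNP inside the window is below
the threshold. Harmonization aligns outcome records to the exposure's effect
allele (sign flip and EAF complement), resolves strand-complement codings for
non-palindromic SNPs, and drops palindromic (A/T, C/G) SNPs whose EAF falls in
the configurable ambiguity window (0.42, 0.58) in either study.

The primary estimator is inverse-variance-weighted (IVW) meta-analysis of
per-SNP Wald ratios $b_i = \beta_{out,i}/\beta_{exp,i}$ with first-order
weights $w_i = (\beta_{exp,i}/se_{out,i})^2$:
$$\hat\beta = \frac{\sum w_i b_i}{\sum w_i}, \qquad
  se_{fixed} = \Big(\sum w_i\Big)^{-1/2}.$$
The random-effects flavor is multiplicative: the reported SE is
$se_{fixed}\sqrt{\max(1, Q/(k-1))}$ with $Q = \sum w_i(b_i-\hat\beta)^2$.
Because the inflation factor is floored at 1 the reported p-value is slightly
conservative under exact homogeneity, and never anticonservative; the
untruncated `pval_fixed` is also returned, and calibration tests use it.
The Wald-ratio SE uses the first-order delta approximation
$se_{out}/|\beta_{exp}|$ — the standard default, exact in the simulator's
strong-instrument regime.

MR-Egger regresses outcome on exposure betas with a free intercept and
weights $1/se_{out}^2$ after orienting every pair so $\beta_{exp}\ge 0$ (this
removes the intercept's sign indeterminacy; it also means simulated
directional pleiotropy must act on the oriented scale, see below). Standard
errors carry the same floored multiplicative overdispersion; tests are on
$t_{k-2}$. Sensitivity analyses comprise Cochran's $Q$ ($\chi^2_{k-1}$ upper
tail), leave-one-out IVW (flagging SNPs whose removal moves $\hat\beta$ by
more than one fixed-effect SE or crosses $P = 0.05$), radial per-SNP $Q_i$
contributions against a Bonferroni-adjusted $\chi^2_1$ quantile
(report-only by default — whether outliers were excluded before the primary
analysis is not specified in the source procedure, so exclusion is opt-in),
and Steiger filtering with $r^2 = t^2/(t^2+n-2)$ per trait (an EAF-based
$2p(1-p)\beta^2$ estimator is available behind `method = "eaf"`). No genomic
region is excluded by default — notably the APOE locus is retained — but
`exclude_region = "chr:start-end"` allows the opposite.

An association qualifies iff IVW $P<0.05$, Egger intercept $P>0.05$, and
$Q$-test $P>0.05$; all three sub-verdicts are recorded.

# Network integration

Qualified forward associations form a directed trait graph (trait identity =
dataset id; parallel qualified results collapse into an integer edge weight).
Community detection uses Walktrap with walk length 4 on the weighted
undirected projection — Walktrap is defined on undirected graphs, and the
weight carries the multiplicity of independent qualified results; weighting
can be disabled. The modularity-maximizing cut is used and the module count
is emergent, never forced. Core relationships are exactly the intra-module
edges; the bidirectional filter retains forward pairs in the core set and
reverse pairs that exactly invert one. Instrument frequency is counted per
(source, direction) stratum, with lexicographic SNP-id tie-breaks.

Gene mapping is positional: SNP positions are 1-based and converted once to
0-based; annotation is BED4 (0-based half-open). Distance is 0 inside a gene,
otherwise the gap to the nearest represented base; a SNP maps to the
minimum-distance gene iff the gap is $\le$ 50,000 bp (inclusive). Ties break
by smaller start, then symbol; "chr1"/"1" naming is normalized at load.

# Enrichment

One-sided hypergeometric over-representation with all counts intersected
against the background, which defaults to the union of genes across the
(filtered) collection; a supplied background overrides. Query genes outside
the background are dropped before counting — the source procedure does not
state whether it intersected, and intersection is the standard choice. Set
sizes are bounded to [5, 2000] after background intersection. $P(X\ge k)$ is
the survival function at $k-1$; Benjamini–Hochberg adjustment runs across all
tested sets with significance at FDR < 0.05.

# Pathway-restricted machine learning

Preprocessing is (1) per-gene Z-scoring with the sample SD, (2) variance
filtering at $10^{-8}$, (3) two-group ANOVA-F selection at $P<0.01$; if
fewer than two genes survive, the ten smallest-$p$ genes are kept (the
"dynamic adjustment" of the feature count, logged). During 10-fold stratified
cross-validation the preprocessing is fitted inside each training fold —
fitting it once globally leaks test information — but a
`global_preprocess = TRUE` switch reproduces the global pre-modeling pipeline.
Fold counts are lowered to the minimum class count when necessary. Metrics
are fold-averaged: AUC (rank-based), accuracy, F1, precision, recall and
Cohen's kappa at a 0.5 score threshold.

The default suite spans the classical tiers: ridge logistic regression
(glmnet), k-nearest neighbors (FNN), a primal squared-hinge linear SVM, and
random forest / extremely randomized trees / gradient boosting built on the
package's compiled CART backend. The deep tabular architectures are out of
scope; the `ml_model()` interface accepts adapters. All model randomness is
driven by seeds derived from the harness seed, so fits are reproducible.

Composite ranking sums each model's per-metric rank (1 = best, ties
averaged) over the six metrics; the top five models contribute importances —
intrinsic (coefficient magnitude or split gain) where available, otherwise
permutation importance (mean AUC drop over column shuffles). "Weighting by
the corresponding model's composite rank" is ambiguous — literal
multiplication by the rank would reward worse models — so the default is
inverse-position weights $1/r$ for the model in top-5 position $r$; vectors
are clipped at zero and normalized to sum 1.

# Gene-scoring cascade

* CMPS: mean of the six metrics with kappa mapped $(\kappa+1)/2$. The other
  five metrics are natively 0–1, so this affine reading keeps the score
  independent of which other models were evaluated; min–max normalization is
  available behind a flag.
* PWIS: raw importance × the reporting model's CMPS.
* GPS (per dataset): sum of a gene's PWIS over pathways and models; the top
  $\lceil 0.01\,N\rceil$ genes (never fewer than one, so small synthetic runs
  still emit a list) are retained, ties broken by appearance count then
  symbol.
* DSS / HGS: $(\sum \text{PWIS}) \times \ln(1 + \text{hits})$ within a
  dataset / across all datasets. The $+1$ is deliberate: the source analysis
  ranks a single-hit gene at the top of one cohort, which a bare
  $\ln(\text{hits})$ factor would zero out; $\ln(1+h)$ keeps a single hit at
  $\ln 2$.

These formulas are isolated in one module so alternates can be swapped.

# Chemical–gene networks

Hub chemicals are ranked by the number of *distinct* prioritized gene targets
(multiple curated actions on one gene count once; interaction directions are
collapsed before degree counting), ties broken by name, top five kept.
Louvain community detection runs on the simple undirected bipartite graph
with sorted node order and a fixed seed, making the partition deterministic.
Cross-disease integration unions the selected chemicals' edges with disease
provenance and counts per-gene convergence as distinct selected chemicals —
a chemical selected in several diseases counts once.

# In vivo differential expression and target ranking

Per-gene two-group linear models on log2-scale expression (linear input is
detected heuristically — any value above 30 — and log2(x+1)-transformed).
Residual variances are shrunk with an empirical-Bayes scaled-F prior fitted
by log-variance moment matching (the same estimator as the established
microarray moderated-t machinery, against which the implementation is tested
to machine precision); when the observed log-variance spread falls below the
sampling floor there is no positive prior-df solution and the implementation
falls back to $d_0 = 10^6$ with all genes shrunk to the common variance.
Moderated $t$ is referred to $d_0 + d_g$ df with BH adjustment. A gene with
zero residual variance in both groups is reported with $p = 1$ and flagged
rather than moderated. Fold changes are reported both as log2 mean
differences and as the linear-scale mean ratio (model/control). The
"overall variance" used downstream is pooled across all samples —
within-group pooling is a defensible alternative, but the pooled reading
matches a variance metric meant to capture dynamic, responsive genes.

DEGs require uncorrected $p < 0.05$ *and* $|\log_2 FC| > 1$, both strict.
The Comprehensive Score ranks each DEG on chemical connectivity, $|\log_2
FC|$, and overall variance — each descending, rank 1 = largest, ties
averaged — and sums the three ranks (lower total = better). "Higher is
better" for all three raw metrics reproduces the published ordering pattern
of top-tier targets; the arithmetic behind the published score values is not
stated, so sum-of-ranks is the default and the formula is isolated for
replacement.

# The synthetic world

The generators state a world; their defaults are not tuned to test outcomes.

* **GWAS pairs.** True instrument effects $\gamma_j$ are uniform on
  [0.03, 0.08] on the standardized-trait scale — with $n = 10^5$ and the SE
  model $1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,n}$ this keeps default
  instruments genome-wide significant, mirroring post-selection instrument
  strength. Effect alleles are coded as the exposure-increasing allele
  (all $\gamma_j > 0$): directional pleiotropy is added as a constant
  $\alpha$ on this oriented scale, which violates InSIDE and gives the Egger
  intercept a usable alternative; with randomly signed $\gamma_j$ the
  orientation flip inside Egger would cancel the planted pleiotropy. The SE
  model makes Steiger's $t^2/(t^2+n-2)$ exact under the generative model.
  LD is generated directly as a block-constant $r^2$ matrix consumed by
  clumping; no individual-level genotypes are simulated.
* **Trait panels.** Ordered trait pairs carry a true causal link with
  probability `intra_edge_prob` within a planted module and
  `inter_edge_prob` between (defaults 0.9 / 0.05 — dense enough for
  community recovery, sparse enough for non-trivial structure).
* **Expression.** Gaussian noise with case-mean shifts of
  `effect_shift` × `noise_sd` restricted to active gene sets. This emulates
  normalized microarray/RNA-seq matrices at the level the pipeline consumes;
  it does not model count noise, library size, or batch structure, so a green
  test establishes harness correctness, not robustness to those artifacts.
* **Chemical edges** plant hub chemicals with specified distinct-gene
  degrees over a background of degree 1–3. **In vivo matrices** plant DEGs
  at specified log2 fold changes with $n = 3$ per group — deliberately the
  small-$n$ regime the moderated-t machinery exists for.

Every generator takes one integer seed; independent streams are derived with
a counter-based splitter (`child_seed`), so adding a stream never perturbs
another, and identical seeds give byte-identical outputs.

# Numerical and engineering notes

* All ranks use average ties; all "top" orderings have deterministic
  symbol-based tie-breaks, so outputs are order-invariant.
* The CART backend draws randomness from R's RNG, so `set.seed()` pins
  forests and boosting exactly; Louvain and Walktrap run under fixed seeds.
* The end-to-end demo (`run_demo()`) runs all eight stages on one CPU in
  well under a minute at the default synthetic sizes, and reruns are
  byte-identical given the seed.
* Acceptance tests that repeat the cascade many times scale the suite down
  (fewer trees, 5 folds, 5 permutation repeats) to stay inside the stated
  runtime budgets; defaults remain 10 folds and the published thresholds.

# Known limitations

Weighted-median/mode estimators, MR-PRESSO and multivariable MR are out of
scope, as are eQTL/colocalization-based gene assignment, ranked GSEA,
hyperparameter search, deep tabular models, and read-level RNA-seq
processing. The expression generator's Gaussian world cannot exercise
count-model corner cases, and the published study's numeric results depend
on external versioned resources and are not reproduction targets.
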