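# nexuslipid

Metabolic disorders (type 2 diabetes, obesity, hypertension, NAFLD) and
neurocognitive diseases (Alzheimer's disease, dementia) co-occur far more
often than chance, but observational associations cannot say which condition
drives which. `nexuslipid` is an R package for epidemiologists and systems
biologists who want to dissect that comorbidity with a reproducible,
fully tested multi-stage pipeline:

1. **Bidirectional two-sample Mendelian randomization** across a panel of
   trait pairs, with instrument selection (P < 5×10⁻⁸, LD clumping
   r² < 0.001 / 1,000 kb), allele harmonization, random-effects IVW,
   MR-Egger, Cochran's Q, leave-one-out, radial outliers and Steiger
   directionality filtering, ending in a three-criterion qualification rule.
2. **Network-guided filtering**: qualified causal links form a trait graph,
   Walktrap communities define modules, and only intra-module ("core")
   relationships — and reverse results exactly inverting them — survive.
3. **Instrument prioritization and gene mapping** (recurrence counting per
   source and direction; nearest gene within ±50 kb, BED conventions).
4. **Hypergeometric gene-set enrichment** (GMT collections, 5–2000 set-size
   bounds, BH-FDR < 0.05).
5. **Pathway-restricted machine learning**: 10-fold stratified CV over a
   six-model suite with six metrics, composite ranks, and importance
   extraction.
6. **A gene-scoring cascade** — Composite Model Performance Score,
   Performance-Weighted Importance, per-dataset Gene Prioritization (top 1%),
   and log-appearance-weighted Dataset-Specific and Holistic Gene Scores.
7. **Chemical–gene hub networks** (top-5 hubs by distinct prioritized
   targets, Louvain communities, cross-disease convergence).
8. **In vivo differential expression** with an empirical-Bayes moderated t
   (DEGs at P < 0.05 and |log₂FC| > 1) and a Comprehensive Score ranking
   targets by summed ranks of chemical connectivity, |log₂FC| and variance.

The core MR estimator is inverse-variance-weighted meta-analysis of Wald
ratios b_i = β_out,i/β_exp,i with weights w_i = (β_exp,i/se_out,i)²:

    β̂ = Σ wᵢbᵢ / Σ wᵢ,   se = (Σ wᵢ)^(-1/2) · √max(1, Q/(k−1))

Every input the pipeline consumes can be produced by seeded synthetic
generators with planted ground truth (causal effects, pleiotropy,
LD blocks, trait modules, pathway signal, hub chemicals, DEGs), so the whole
chain is testable end to end without external data.

## Worked example

```r
library(nexuslipid)

# simulate one exposure -> outcome GWAS pair with a true effect of 0.2
p <- simulate_gwas_pair(gwas_sim_config(n_instruments = 40, beta_causal = 0.2,
                                        n_exposure = 2e5, n_outcome = 2e5,
                                        seed = 42))
qa <- mr_run(p$exposure, p$outcome, p$ld,
             exposure_id = "T2D", outcome_id = "dementia",
             direction = "forward", source_id = "demo")
```

This prints (via the formatting in the example script):

```
IVW beta = 0.211 (SE 0.011), OR = 1.234 [1.208-1.262], P = 3.86e-80, nsnp = 33
Egger intercept P = 0.31, Q P = 0.62, qualified = TRUE
```

Reading: of the 40 simulated instruments, 33 survive clumping,
harmonization and Steiger filtering; the IVW estimate recovers the planted
causal effect (0.211 vs true 0.2, within one SE), the odds-ratio scale says a
23% risk increase per unit exposure; the Egger intercept and Q tests find no
pleiotropy or heterogeneity, so the association qualifies under the
three-criterion rule.

The full synthetic demonstration — all eight stages, with TSV/JSON outputs
and a manifest — runs in seconds and is byte-reproducible for a fixed seed:

```r
res <- run_demo(seed = 1, out_dir = "demo_run")
#> [nexuslipid] stage synthio ... stage invivo
#> [nexuslipid] done: 8/8 stages completed; outputs in demo_run
```

A thin CLI wraps the same entry points:

```sh
inst/cli/nexuslipid demo --seed 1 --out demo_run
inst/cli/nexuslipid mr --exposure X.tsv --outcome Y.tsv --ld L.tsv --out mr_out
inst/cli/nexuslipid enrich --query genes.txt --gmt c5.gmt
```

## Documentation

See `vignettes/nexuslipid-methods.Rmd` for the statistical models, the
generative assumptions of the synthetic world, all tunable thresholds with
their defaults, and the design decisions taken where the procedure was
genuinely open.
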