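# deepcoxsig

Prognostic-gene discovery from tumor expression profiles with a deep Cox
survival network and hidden-layer permutation importance.

## Who this is for

Analysts with (i) a genes × samples log2 expression matrix for a tumor
cohort plus a small normal-tissue reference, (ii) overall-survival
follow-up (time in months, event indicator), and optionally (iii) clinical
covariates — who want a survival risk model that does not assume linear,
independent gene effects, and a compact, interpretable gene signature
extracted from that model. A synthetic cohort generator with known ground
truth makes the whole chain testable without any external data.

## The method

1. **Filter.** Per-gene Welch t-tests of tumor vs normal on the log2 scale;
   keep genes with *p* < 0.01 and |log2 FC| ≥ 1 (2-fold change), with the
   false-discovery rate at that threshold reported from a beta-uniform
   mixture fit of the p-value histogram. Genes correlated above |r| = 0.8
   are pruned to one representative each.
2. **Train.** A multilayer perceptron (up to two hidden layers, default
   82 → 27, batch norm + ReLU, single linear output) maps expression to a
   log-risk score `r_i` and is trained by full-batch Adam on the negative
   Cox log partial likelihood

   `L = − Σ_{i: event} [ r_i − log Σ_{j: t_j ≥ t_i} exp(r_j) ] + λ₂ Σ‖W‖²`

   (Breslow ties), on survival-time-stratified 80/10/10 partitions, keeping
   the epoch with the best validation concordance.
3. **Explain.** Each input gene is permuted across samples (5 seeded
   repeats); the mean absolute change of each last-hidden-layer node
   activation flags per-node important genes (delta > across-gene mean +
   1.96 SD). A gene's occurrence frequency across the 27 nodes is compared
   with a Binomial(27, q̂) null; genes above the p < 0.01 occurrence
   threshold `k_min` form the signature.
4. **Compare & validate.** Ridge / adaptive-lasso / elastic-net Cox models
   (proximal gradient, 9-fold cross-validated λ-min) serve as comparators;
   Cox proportional-hazards models, Harrell's concordance, Kaplan–Meier
   curves, and log-rank tests on a median split of the prognostic index
   `x'β` validate the signature on held-out samples.

## Worked example

```r
library(deepcoxsig)

cfg <- pipeline_config(
  synth = synthetic_config(n_tumor = 400, n_genes = 500,
                           n_informative = 20, seed = 7),
  penalties = list(),  # skip the penalized comparators for a quick run
  seed = 7)
res <- run_pipeline(cfg)
```

On this cohort — 400 tumors, 500 genes of which 20 drive a Weibull
proportional-hazards event process (a fifth of them through a quadratic
term), ~30% censoring — the run prints:

```
genes after DE filter + pruning: 154
best epoch: 44 | validation C-index: 0.724 | test C-index: 0.806
occurrence threshold k_min: 6 of 27 nodes
signature: 15 genes; 13 of the 20 planted prognostic genes, 2 background
median-split log-rank on the held-out partition: chi2 = 14.48 , p = 0.000142
```

Reading this: the filter reduced 500 genes to 154 network inputs; the
trained network ranks held-out patients' survival clearly better than
chance (concordance 0.5 = random); the binomial occurrence null puts the
signature cutoff at 6 of 27 nodes; and the extracted signature is
dominated by truly prognostic genes, separating high- from low-risk
patients on the untouched test partition.

The packaged reference frequency table reproduces the published 39-gene
signature at its occurrence threshold:

```r
sig39 <- extract_signature(gbm_gene_frequency(), k_min = 10)
length(sig39$gene_ids)   # 39
sig39$gene_ids[1:3]      # "TNR" "GAD1" "POSTN"
```

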