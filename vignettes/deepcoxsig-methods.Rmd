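---
title: "Deep Cox networks and permutation-derived gene signatures: methods"
author: "deepcoxsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep Cox networks and permutation-derived gene signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Given bulk tumor expression profiles, a matched normal-tissue reference, and
overall-survival follow-up, we want (i) a risk model that predicts survival
from expression without assuming each gene acts linearly and independently,
and (ii) an interpretable, compact gene signature extracted from that model.
`deepcoxsig` implements the full discovery chain: differential-expression
filtering, a feed-forward network trained on the Cox partial likelihood,
hidden-layer permutation importance with occurrence-frequency signature
extraction, penalized Cox comparators, and classical survival validation.

# The model

## Cox partial likelihood as a network loss

For patient $i$ with observed time $t_i$ and event indicator $\delta_i$, the
network produces a scalar log-risk $r_i = f_\theta(x_i)$. The training loss
is the negative log partial likelihood

$$\mathcal{L}(\theta) = -\sum_{i:\,\delta_i = 1}
  \Big[ r_i - \log \sum_{j:\,t_j \ge t_i} e^{r_j} \Big]
  \; + \; \lambda_2 \sum_\ell \lVert W_\ell \rVert_2^2 ,$$

with Breslow handling of tied event times and a log-sum-exp-stabilized risk
set accumulation. No baseline hazard is estimated; like the classical Cox
model the loss depends only on risk *ranking* within risk sets and is
invariant to adding a constant to all risks (asserted in the tests at
1e-8). Breslow ties were chosen for internal consistency between the
network loss, the penalized comparators, and the `survival::coxph` fits
(`ties = "breslow"`); Efron weighting is not offered.

## Architecture and training

The network is an MLP with up to two dense hidden layers (default 82 then
27 nodes, the published operating point), each followed by batch
normalization and ReLU, and a single linear output node. Inputs are z-scored
per gene on the training partition, and the transform is frozen for
validation, test, and importance passes.

Training is full-batch Adam on the penalized loss. Design choices that were
genuinely open:

* **Optimizer.** No optimizer is prescribed by the method; full-batch Adam
  was chosen because the cohort fits in memory, gradients are exact, and a
  seeded run is bit-reproducible. The analytic backpropagation (including
  the train-mode batch-norm backward pass) is verified against central
  finite differences to ~1e-9 in the tests.
* **Checkpointing.** Up to 1000 epochs are allowed; the returned model is
  the epoch with the highest *validation concordance* (the method's own
  selection rule). The final-epoch parameters are also returned, since
  optimization-endpoint properties (e.g. penalty dominance) concern them.
* **Batch-norm statistics.** Running means/variances are exponential moving
  averages (momentum 0.9); inference always uses the stored statistics, so
  eval-mode forward passes — and therefore permutation importance — are
  deterministic pure functions.
* **L2 strength.** The loss is the *unnormalized* total partial likelihood,
  so `l2_coefficient` lives on that scale. The default (1) was selected by
  validation concordance on the default synthetic cohort; it is a tuned
  hyperparameter, as the method prescribes, not a universal constant.

Model selection across architectures (`hyperparameter_search`) is an
exhaustive evaluation by validation concordance with ties broken toward
fewer parameters; `rotate_validation` reports the mean and SD of validation
concordance when each non-test partition takes a turn as the validation set.

## Gene filtering

`diff_expression` performs a per-gene Welch two-sample t-test of tumor vs
normal on the log2 scale (the method's own test is unnamed; Welch on
normalized log intensities is the field default and is recorded as such).
Selection requires `p < 0.01` *and* `|log2 FC| >= 1` (a 2-fold change; the
fold-change cut is interpreted on the log2 scale). The beta-uniform mixture
(BUM) model $f(p) = \lambda + (1-\lambda)\,a\,p^{a-1}$ is fitted to the
p-value histogram by bounded maximum likelihood from a deterministic grid of
starts, and the Pounds–Morris upper-bound FDR at the threshold,
$\widehat{\mathrm{FDR}}(\tau) = \pi_{ub}\tau / F(\tau)$ with
$\pi_{ub} = \lambda + (1-\lambda)a$, is *reported* alongside the selection
rather than altering the cutoff — the selection threshold itself stays at
the stated p and fold-change arms.

Correlation pruning groups genes by single linkage on $|r| > 0.8$ and keeps
the highest-variance representative per group (lexicographically smallest id
on ties). Because single linkage closes transitively, no two retained genes
exceed the threshold. Survival-time-stratified partitioning sorts samples by
time, forms consecutive rank blocks of size $k$, and deals each block to the
$k$ partitions in seeded random order — this construction *guarantees* the
partitions preserve the survival-time distribution (max KS distance to the
pooled distribution is asserted < 0.15 in tests) with sizes differing by at
most one.

## Permutation importance and signature extraction

With the trained model frozen in eval mode, one input gene at a time is
permuted across samples (5 seeded repeats, seeded per gene id so results do
not depend on iteration order) and the mean *absolute* change of each
last-hidden-layer node activation — and of the output risk — is recorded.
Absolute rather than signed changes are averaged because signed changes
cancel for symmetric perturbations; a `signed_mean` variant is available
behind the `statistic` argument. Because only one input row changes, the
implementation propagates a rank-one update of the first-layer
pre-activations rather than recomputing the input matmul, which makes the
500-gene scan take seconds.

Per node, a gene is flagged *important* when its delta exceeds the
across-gene mean by 1.96 across-gene SDs (`mean + z * SD`,
`z = qnorm(1 - (1 - ci_level)/2)`); the rule is one-sided since deltas are
nonnegative. A percentile variant was considered and rejected: with a few
hundred genes the upper percentile is estimated from a handful of order
statistics and flaps between seeds.

Gene occurrence frequency is the count of nodes flagging the gene. The
occurrence threshold $k_{\min}$ is the smallest $k$ for which
$P(K \ge k) < 0.01$ under $K \sim \mathrm{Binomial}(n_{\text{nodes}},
\hat q)$ with $\hat q$ the pooled per-node flag fraction. The binomial null
treats nodes as independent; in truth flags correlate across nodes (they
share one network), so the null is approximate — the package keeps it as
the default because it is parameter-free and reproduces the qualitative
behavior that occurrence at many nodes is rare, but the occurrence counts
themselves are always returned so a user can inspect the full distribution.
The signature is all genes with frequency $\ge k_{\min}$, in descending
frequency. The packaged reference frequency table reproduces the published
39-gene signature exactly at $k_{\min} = 10$.

## Penalized Cox comparators

Ridge, adaptive lasso, and elastic net maximize the penalized partial
log-likelihood with penalties $\lambda\beta_j^2$,
$\lambda w_j |\beta_j|$ ($w_j = 1/|\beta_j^{\text{ridge}}|$, capped at 1e8),
and $\lambda(\alpha|\beta_j| + (1-\alpha)\beta_j^2/2)$ respectively — the
elastic-net $\tfrac12$ factor follows the printed penalty form exactly, and
the objective is implemented as minimizing negative log partial likelihood
plus penalty. The solver is proximal gradient with weighted soft
thresholding, backtracking line search on the smooth majorizer, cautious
step re-expansion, warm starts down the $\lambda$ path, convergence at max
coefficient change < 1e-6 (10,000 iteration cap), and a KKT check
(`kkt_violation`). $\lambda$ selection uses 9-fold survival-time-stratified
cross-validation of the Verweij–van Houwelingen deviance
$-2\,[\ell(\hat\beta_{-f}) - \ell_{-f}(\hat\beta_{-f})]$; only the
minimum-deviance $\lambda$ is selected (the one-SE rule is deliberately not
offered, as it is numerically unstable here). The default grid is 50
log-spaced points spanning four decades below the smallest all-zero-solution
$\lambda$. $\alpha = 0.5$ is the elastic-net default, exposed as
configuration. Feature importance is $|\beta|$ in descending order.

## Survival statistics

Classical machinery is delegated to the `survival` package behind the
module surface: `coxph` (Breslow), `cox.zph` with the event-rank time
transform for the Grambsch–Therneau proportional-hazards test, `survfit`
for Kaplan–Meier, `survdiff` for the log-rank test. Authored pieces:
Harrell's concordance (usable pairs = strictly shorter time with an event;
risk ties count one half; equal observed times are not usable — matched
exactly against a brute-force pair enumeration in the tests), the
prognostic index $x'\beta$ (no centering), and the median split (ties to
the low-risk group, a recorded convention). Dichotomization thresholds for
node outputs (e.g. "node $\ge 1.6$", stratified) are accepted as
configuration, not derived. A near-singular augmented design (condition
number > 1e8) raises a collinearity warning, mirroring what happens when a
node output duplicates a clinical covariate.

# The synthetic cohort generator

The generator exists so that every stage is testable against known ground
truth without downloads. It emulates:

* log2-scale expression around mean 7, unit variance, with
  block-equicorrelated background genes (blocks of 10, $\rho = 0.6$);
* a sparse set of informative genes (default 20) driving a Weibull
  proportional-hazards event process (shape 1.2, scale 20 months — median
  survival near 14 months at zero risk, a realistic figure for an
  aggressive brain tumor cohort) through unit log-hazard coefficients of
  alternating sign; a fraction (default 0.2) act through a centered,
  variance-normalized quadratic term rather than linearly;
* independent exponential censoring with the rate solved numerically so the
  achieved censoring fraction matches the target (default 0.3; asserted to
  ±0.05 at n ≥ 200 in the tests);
* tumor-vs-normal differential expression: informative genes are shifted
  +1.5 log2 units against the normal reference, and — crucially — a
  configurable fraction (default 0.3) of *background* genes is also
  differentially expressed with random sign but **no** effect on the
  hazard. Real tumor transcriptomes are dominated by such genes: roughly a
  third of the transcriptome survives a 2-fold filter while only a small
  minority is prognostic. Without them, the differential-expression filter
  would reduce the synthetic input to essentially the causal genes alone
  and the downstream occurrence-frequency analysis would be degenerate
  (no outliers among uniformly important inputs);
* clinical covariates generated independently of expression except an
  optional age–risk correlation (default 0.3), keeping ground truth
  factorizable for tests.

Event times use inverse-transform sampling from
$S(t) = \exp[-(t/\text{scale})^{\text{shape}} e^{\text{lp}}]$. A single
seed fans out to per-stage seed streams (an affine step modulo $2^{31}-1$),
so identical configurations are bit-reproducible and stages can be rerun in
isolation.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe- and array-level artifacts (the raw-array
processing chain is out of scope), batch effects, co-expression *around the
causal genes* (informative genes are deliberately mutually uncorrelated
singletons so that "non-informative" is well defined for recovery tests;
in real tumors prognostic genes sit inside co-expression modules and
importance spreads across module members), non-Gaussian expression
heavy-tails, and informative censoring.

# Numerical choices and degenerate inputs

* Risk-set sums and the partial likelihood use log-sum-exp; the gradient is
  analytic and tested against finite differences.
* Constant genes: correlation with a constant gene is defined as 0 (the
  gene is retained by pruning); constant covariates are rejected by
  `fit_cox_ph` with the term named.
* A gene disconnected from the first layer has exactly zero permutation
  delta; a constant gene's permutations are no-ops.
* BUM fitting bounds $\lambda, a$ to $[10^{-6}, 1 - 10^{-6}]$ and takes the
  best of a 16-point start grid, making the "optimizer" deterministic.
* `occurrence_threshold` returns 1 with a warning when nothing is flagged,
  and `n_nodes + 1` when even full occurrence is not surprising.
* The pipeline falls back to the `min_genes` smallest-p genes when fewer
  pass the filter (e.g. a null cohort), so downstream stages stay defined;
  the manifest records that the fallback fired.

# Problem sizes used in the packaged checks

The test suite and the acceptance script run the pipeline on a synthetic
cohort of 400 tumors x 500 genes with 20 informative genes (the filtered
network input is ~150 genes), train for up to 1000 epochs, and evaluate
permutation importance with 5 repeats; simulation-based statistical checks
use 60–500 replicates at n = 100–2000. These sizes were chosen so each
property is measured with adequate power while a full run stays in the
minutes range on one CPU.

# Known limitations

* The binomial occurrence null ignores cross-node flag dependence; with few
  input genes or strong overfitting the computed $k_{\min}$ can be
  permissive. Inspect the returned frequency table.
* On unfiltered high-dimensional input (hundreds of genes at a few hundred
  samples) the strongest spurious correlates are genuinely used by any
  regularized fit and can enter the signature; the differential-expression
  pre-filter is part of the method, not an optional convenience.
* Harrell's C treats equal observed times as non-comparable; packages using
  other tie conventions will differ in the third decimal on tied data.
* The trained network is seed-reproducible only under identical BLAS
  arithmetic.
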