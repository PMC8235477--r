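---
title: "Methods: multi-task variational embedding of multi-omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task variational embedding of multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omixtask)
```

## Model

`omixtask` assumes that the several omics blocks of one sample — gene
expression, DNA methylation beta values, miRNA expression, all scaled to
$[0,1]$ — are generated from a single low-dimensional latent vector
$z \in \mathbb{R}^p$. The embedding module is a variational autoencoder:
per-block encoder layers (LeakyReLU), a shared fusion layer, and two linear
bottleneck maps giving the posterior mean $\mu$ and log-variance; sampling
uses $z = \mu + \sigma\odot\epsilon$. Decoders mirror the encoder and end
in sigmoids, so reconstructions live in $(0,1)$ and binary cross-entropy is
a valid reconstruction likelihood for $[0,1]$-valued data. The embedding
loss is the per-block BCE (averaged over the $M$ blocks) plus the diagonal
Gaussian KL term in closed form.

Downstream heads consume $z$ (the sampled draw during training, the
deterministic $\mu$ at inference, so exported latents and predictions are
reproducible): a softmax classifier, a one-neuron regressor, and a
discrete-time survival head. The survival head is multi-task logistic
regression (MTLR): the time axis is divided into $m$ intervals
$l_i=[t_{i-1},t_i)$ with $t_0=0$ and $t_m \ge \max(T)$; the head's $m$
logits score the $m{+}1$ monotone outcome sequences (death in interval
$1..m$, or survival past $t_m$), normalised by enumerating all of them.
The label encoding sets $y_i = 1$ iff death occurred by $t_i$
(a death at exactly $t_i$ closes interval $i$). The likelihood is invariant
to the choice between this and the mirrored convention as long as encoding
and denominator agree, which the brute-force enumeration tests pin down.

**Censoring.** The uncensored MTLR likelihood covers only fully observed
outcome sequences. A subject censored at $T$ is known alive at every grid
point $t_i \le T$, so we marginalise: the loss is the negative log of the
total outcome mass over the admissible range (death in any later interval,
or survival). Both cases reduce to $-\log \sum_{j \in [lo, hi]} p_j$ with a
contiguous admissible range, which keeps the gradient a difference of two
cumulative pmfs.

**Risk and curves.** Each subject gets $S(t_k) = \sum_{j\ge k} p_j$ and a
risk score equal to the sum of the discrete hazards
$h_i = p_{i-1}/S(t_{i-1})$; an interval whose conditioning mass is zero
contributes the defined limit 1. The concordance index is invariant to any
monotone transform of risk, so the hazard-sum reading is interchangeable
with cumulative-incidence alternatives for ranking purposes.

**Multi-task balancing.** The joint loss is
$\lambda L_{\text{embed}} + \frac{1}{K}\sum_k w_k L_k$. GradNorm treats the
$w_k$ as learnable: per-task gradient norms
$G_k = \lVert\nabla_\theta (w_k L_k)\rVert_2$ are computed at the weights
of the $\mu$ bottleneck map — the last shared encoding layer, the natural
GradNorm reference point — and pulled toward
$\bar G \cdot r_k^\alpha$, where $r_k$ is the task's loss ratio relative to
its initial Phase-3 loss, normalised to mean 1. The targets are held
constant during the weight update (one analytic gradient step, since
$\partial G_k/\partial w_k = G_k / w_k$), and weights are renormalised to
sum to $K$ after every step. With a single task, or GradNorm disabled,
training is exactly single-task optimisation.

**Three phases.** Phase 1 trains the embedding alone (unsupervised; usable
on its own for dimensionality reduction and latent export). Phase 2 trains
the heads on the frozen embedding. Phase 3 fine-tunes everything jointly
with GradNorm active; initial losses $L^0_k$ are recorded at its first
iteration because the weights are static before that. Each phase gets a
fresh Adam optimiser. The freezing contract is tested bit-exactly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `latent_dim` | 16 | latent dimension $p$; 2–3 for direct visualisation |
| `hidden_per_block` | 64 | encoder width per omics block |
| `hidden_fusion` | 64 | shared fusion width |
| `head_hidden` | 32 | hidden width of each downstream head |
| `lambda` | $0.01\,p/\bar d$ | embedding-loss weight in Phase 3 |
| `alpha` | 1 | GradNorm asymmetry strength |
| `m` | 256, capped at the event count | survival intervals |
| `epochs` | 10 / 30 / 30 | Phase 1 / 2 / 3 epochs |
| `lr`, `lr_gamma`, `lr_step` | 1e-3, 0.5, 20 | Adam rate, halved every 20 epochs per phase |
| `weight_decay` | 1e-4 | L2 on weights (biases exempt) |
| `dropout` | 0 | dropout on head hidden layers |
| `gradnorm_lr` | 0.025 | task-weight step size |

The $\lambda$ heuristic keeps $\lambda L_{\text{embed}}$ on the order of
the downstream losses when BCE is summed over features: with $\bar d$
features per block the reconstruction term scales like $\bar d$, so
$0.01\,p/\bar d$ makes the product roughly $0.01\,p$. The feature-sum BCE
reduction (rather than the mean) is deliberate: with $d \gg p$ a
feature-mean reconstruction term would be drowned by the KL term and the
posterior would collapse to the prior; `recon_reduction = "mean"` is
available for experimentation. The quantile grid scheme balances event
counts per interval, which keeps per-interval logits identifiable;
`"uniform"` is available. Interior quantile boundaries are computed as
exact order statistics (rank $\lceil nk/m \rceil$) because generic
quantile interpolation can duplicate boundaries through floating-point
fuzz when $m$ equals the event count.

Regression targets are z-scored on the training split internally and
predictions back-transformed. Raw ages have MSE on the order of hundreds
of years²; before GradNorm activates in Phase 3 the downstream sum is
unweighted, and an unstandardised regression loss would dominate Phase 2.

Batch normalisation is not implemented; dropout, weight decay and the step
learning-rate schedule are. At the layer widths used here (tens of units)
batch-norm adds substantial backprop complexity without measurable benefit
on the synthetic task, and the remaining regularisers cover the
overfitting risk.

## Preprocessing

Matrices are features × samples on disk (Xena convention) and samples ×
features in memory. Methylation probe filtering removes the union of
user-supplied criterion lists (Y-chromosome, SNP-overlapping, non-uniquely
mapping, non-EPIC, SNP-assay, non-CpG probes) plus probes missing in more
than 10% of samples; expression filtering drops Y-chromosome genes and
genes that are exactly zero in every sample. Remaining gaps are imputed by
the feature mean. Min–max normalisation to $[0,1]$ is per feature and — by
default — fit on the training split only, with held-out samples clamped to
$[0,1]$: global normalisation leaks test-set ranges into training, so the
stricter per-split fit is the default and a global option restores the
simpler behaviour. Whether per-feature or global min–max is the "right"
reading is genuinely open; per-feature is chosen because constant features
otherwise dominate the scale. Reference probe lists are user-supplied
files, not bundled, since they derive from external array annotations.

Stratified splitting uses largest-remainder allocation within class, so
per-class counts deviate from exact proportionality by less than one
sample; classes with fewer than three members cannot be stratified over
three splits and are routed entirely to training. K-fold partitions deal
shuffled class members round-robin.

## The synthetic generator

The generator is the package's ground-truth instrument: class centroids sit
on scaled coordinate axes of the true latent space (the separation
parameter is exactly the pairwise centroid distance), samples add unit
Gaussian noise, and each omics block is an elementwise sigmoid of a fixed
random linear map of the latent plus Gaussian noise — so all values lie in
$[0,1]$ by construction and one shared latent drives every block. Age is
affine in latent axis 2 (slope 10 years per unit, noise sd 5 years),
gender thresholds axis 3, and death times are exponential with rate
$\lambda_0 \exp(\beta z_1)$. Censoring is independent exponential with its
rate solved numerically so the expected censored fraction matches the
target — the standard survival-simulation device that keeps censoring
non-informative. Default conditions: 600 samples, blocks of 200/300/100
features, 4 classes at separation 5, $\lambda_0 = 0.1$ per unit time,
$\beta = 1$, 30% censoring.

What it does *not* emulate: linkage disequilibrium or CpG-island
correlation structure, batch effects, heavy-tailed expression
distributions, or informative censoring. Passing the recovery tests
therefore shows that the machinery works when its assumptions hold — not
that the same accuracy transfers to real cohorts.

## Evaluation

Macro-averaged F1/TPR/PPV use unweighted class means from one-vs-rest
counts; ROC AUC is one-vs-rest per class (computed via `pROC`) and averaged
unweighted — the one-vs-one variant is a documented alternative, not
implemented. Classes absent from the test truth are excluded from macro
averages; a class with single-valued truth is skipped for AUC with a
warning. Harrell's C-index gives half credit to risk ties and skips time
ties. The Brier score uses inverse-probability-of-censoring weights from
the Kaplan–Meier estimate of the censoring distribution (Graf
decomposition), with $G(t^-)$ evaluated as a left limit; the integrated
Brier score averages the grid points up to the last observed event time,
and times where $G$ has reached zero are dropped with a warning.
Unweighted Brier is available behind a flag.

## Numerical choices

The MTLR pmf and loss use log-sum-exp stabilisation and remain valid for
logits of magnitude $10^3$ (tested). The posterior scale is stored as
log-variance, initialised near zero so $\sigma \approx 1$ at the start.
Constant features map to 0 under min–max. All gradients are analytic and
verified against central finite differences in every phase. Training is
bit-reproducible under a fixed seed (pure R RNG, no threading
nondeterminism).

## Problem sizes in the test suite

The suite exercises the full study at 600 samples and 600 total features
(the generator's default conditions) for end-to-end recovery, a 300-sample
study for the multi-task vs single-task comparison harness, and
80–200-sample studies for mechanism tests; oracle checks (pmf enumeration,
brute-force concordance, finite differences, quadrature) run on grids of
$m \le 10$ and $n \le 20$ where exhaustive computation is exact. These
sizes were chosen so each property is measured where its oracle is
feasible.

## Known limitations

- The CNN-type embedding variant is out of scope; the fully connected
  architecture is the implemented and preferred one.
- No competing risks, time-varying covariates, or Cox partial-likelihood
  baselines.
- GradNorm runs only in Phase 3; whether to adapt weights while the
  embedding is frozen is an open design point, and keeping Phase 2
  weights static makes $L^0_k$ well-defined.
- The prior is a standard Gaussian; mixture priors and graph-structured
  encoders are natural extensions not provided here.
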