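# omixtask

Joint low-dimensional embedding of multi-omics profiles with a variational
autoencoder, plus jointly trained downstream heads for phenotype
classification, age regression and discrete-time survival prediction — one
latent representation serving several clinical prediction tasks at once.

## The problem

Bulk omics profiles (RNA-seq gene expression, DNA methylation beta values,
miRNA expression) have $10^4$–$10^5$ features per sample but carry a shared
low-dimensional biological signal. `omixtask` embeds the blocks of one
sample into a single latent vector and lets supervised heads pull that
latent space toward clinically useful structure: tumour type, age, and
prognosis — trained together rather than as separate pipelines.

## The model

**Embedding.** Per-omics encoders feed a shared fusion layer that produces
the mean $\mu$ and log-variance of a diagonal Gaussian posterior
$q_\phi(z\,|\,x)$ over a latent $z \in \mathbb{R}^p$, sampled with the
reparameterisation trick $z = \mu + \sigma \odot \epsilon$,
$\epsilon \sim N(0, I)$. Mirror-image decoders reconstruct each block
through sigmoid outputs. The embedding loss is the negative evidence lower
bound

$$L_{\text{embed}} = \tfrac{1}{M}\sum_{j=1}^{M}\mathrm{BCE}(x_j, x_j')
  + D_{\mathrm{KL}}\!\left(N(\mu,\sigma)\,\|\,N(0,I)\right).$$

Methylation features can be grouped by chromosome in the first encoder
layer (block-diagonal weights), cutting the parameter count of the widest
layer.

**Heads.** Classification (softmax, cross-entropy), regression (one output
neuron, MSE), and survival: the time axis is split into $m$ intervals
$l_i = [t_{i-1}, t_i)$ and the head emits $m$ logits $y'$ scoring the
$m{+}1$ monotone survival/death sequences — multi-task logistic regression
(MTLR), with

$$P(y\,|\,x) = \frac{\exp\left(\sum_i y_i y_i'\right)}
 {\sum_{j=0}^{m}\exp\left(\sum_{i=j+1}^{m} y_i'\right)}.$$

Censored subjects contribute the marginal likelihood over every outcome
sequence consistent with their last known-alive time. Each subject gets a
full predicted survival curve $S(t_k)$ and a risk score
$r(x) = \sum_i h_i$, the sum of discrete hazards.

**Multi-task balance.** The joint loss is
$L = \lambda L_{\text{embed}} + \tfrac{1}{K}\sum_k w_k L_k$ with learnable
task weights $w_k$ updated by gradient normalisation (GradNorm): per-task
gradient norms at the last encoding layer are pulled toward a common value
modulated by each task's relative inverse training rate, so no head
dominates. Training runs in three phases: (1) unsupervised embedding only,
(2) heads on the frozen embedding, (3) joint fine-tuning with GradNorm.

All networks, losses, backpropagation and the Adam optimiser are
implemented in base R matrix code; no deep-learning framework is required.

## Worked example

```r
library(omixtask)

# synthetic study: 600 samples, 3 omics blocks (200/300/100 features),
# 4 classes, hazard driven by latent axis 1, 30% censoring
res <- synth_generate(synth_config(seed = 7))
ds  <- res$dataset

sp  <- stratified_split(ds$phenotype, "class", c(0.6, 0.2, 0.2), seed = 7)
X   <- lapply(ds$blocks, function(b) prepare_block(b, sp$train)$values)

fit <- train_multitask(
  X, ds$phenotype,
  tasks = list(class = list(type = "classification", label = "class"),
               age   = list(type = "regression",     label = "age"),
               surv  = list(type = "survival")),
  config = train_config(seed = 7),
  train_idx = sp$train, val_idx = sp$val)

met <- evaluate_fit(fit, X, ds$phenotype, sp$test)
met$class$accuracy   # 0.9748
met$age$r2           # 0.8759
met$surv$c_index     # 0.8024
met$surv$ibs         # 0.1039
```

Test accuracy 0.97 means the latent space separates the four planted
classes almost perfectly; age R² 0.88 says most of the variance of the
age label (an affine function of latent axis 2 plus noise) is recovered;
C-index 0.80 means that in 80% of comparable patient pairs the model
assigns the higher risk score to the patient who dies first, and the
integrated Brier score 0.10 measures the calibrated accuracy of the whole
predicted survival curve (0 is perfect, 0.25 is an uninformative constant).

A shell-style interface with `generate` / `train` / `predict` subcommands
is installed at `inst/cli/omixtask.R`:

```sh
Rscript inst/cli/omixtask.R generate --out fx --seed 1
Rscript inst/cli/omixtask.R train --data fx --out run --cv 5 --seed 1
Rscript inst/cli/omixtask.R predict --checkpoint run/fold1/checkpoint.rds \
    --data fx --out predictions
```

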