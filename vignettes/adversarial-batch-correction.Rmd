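---
title: "Adversarial information factorization for batch-effect correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial information factorization for batch-effect correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scaif)
```

## The problem

Single-cell RNA-seq experiments processed in different runs, by different
hands, or on different platforms carry systematic technical variation —
batch effects — that can dwarf the biological differences between cell
types. A useful correction must do two things at once: interleave cells
from different batches (batch mixing) while keeping cells of one annotated
type co-located (cell-type purity). Methods that correct only an embedding
(for clustering) cannot feed downstream analyses such as differential
expression; `scaif` corrects in the original gene space.

## The model

The core of the package is a conditional variational autoencoder trained
under adversarial information factorization. Four networks cooperate and
compete:

* an **encoder** maps a cell's expression vector $x \in \mathbb{R}^d$ to a
  diagonal-Gaussian posterior $\mathcal{N}(\mu_q, \Sigma_q)$ over a latent
  space of dimension $k$, plus predicted batch probabilities $\hat y$;
* a **decoder** reconstructs expression from a latent sample
  $z = \mu_q + \Sigma_q^{1/2}\varepsilon$ and a *batch code* — a point on
  the simplex over batches (one-hot for a real batch, uniform for the
  "average batch", fractional for interpolations);
* a **discriminator** is trained to tell original cells from
  reconstructions (the GAN game), pushing decodes onto the data manifold;
* an **auxiliary classifier** tries to predict the batch from the latent
  representation. Its success is penalized in the encoder objective, so at
  the adversarial equilibrium the latent space carries no batch
  information — the factorization that gives the method its name.

Seven loss terms assemble into two objectives,

$$
\begin{aligned}
L_{enc} &= L_{rec} + \alpha L_{KL} + \rho L_{class} + \beta \hat L_{class}
  - \mu L_{proj} - \delta L_{gan} - \gamma L_{aux},\\
L_{dec} &= L_{rec} + \beta \hat L_{class} - \delta L_{gan} - \mu L_{proj},
\end{aligned}
$$

with $L_{rec}$ the per-cell sum of squared reconstruction errors,
$L_{KL} = \tfrac12(-\log|\Sigma_q| - k + \mu_q^\top\mu_q +
\operatorname{tr}\Sigma_q)$ the closed-form divergence to the standard
normal prior, $L_{class}$ the (optionally class-weighted) cross-entropy of
the encoder's batch head, $\hat L_{class}$ the same cross-entropy after
passing the reconstruction back through the encoder, $L_{aux}$ the
auxiliary classifier's cross-entropy, $L_{proj}$ the sum of cosine
similarities between the reconstruction and its decodes under the average
and a random batch code (maximized, hence the minus sign: reconstructions
under different codes should agree), and $L_{gan}$ the mean of three
cross-entropies scoring the discriminator on original cells,
reconstructions, and decodes of prior samples.

Per minibatch the discriminator is updated first, then the auxiliary
classifier, then the decoder and encoder on their objectives (gradients
for both taken against the freshly updated adversaries from one forward
pass). All four networks are fully connected stacks with leaky-rectifier
activations and per-network Adam optimizers; variances are parameterized
as log-variances.

## Dynamic loss normalization ("dyn")

The seven losses live on wildly different scales (a summed squared error
over thousands of genes versus a cross-entropy of order one). Before
weighting, each loss is divided by its *dynamic normalizer*: the median of
its per-epoch values over a trailing window of 10% of the total epochs
(`dynamic_normalizers()`). After the first window, every normalized loss
has window-median one, so the weights express true relative importance.

Three numerical safeguards make this scheme stable in practice, all on by
default and documented here because they matter:

* **Initial scale.** The epoch-1 normalizers come from a pre-training
  forward pass rather than defaulting to one. Adam's second-moment
  estimate remembers gradient scale for roughly $1/(1-\beta_2)$ steps; a
  thousand-fold scale jump between epochs 1 and 2 would freeze training
  for most of a run.
* **Banding.** In-training normalizers are kept within $[0.02, 50]\times$
  their initial value. A loss that collapses toward zero (a saturated
  discriminator, a vanished KL) would otherwise be amplified without
  bound, and a loss that explodes would lose all restraint; both are
  absorbing states of the raw median scheme.
* **Free bits.** Latent dimensions whose per-dimension KL falls below
  `kl_free_nats` (default 0.25) are exempt from the pull toward the
  prior. Without this, the combination of adversarial pressure and the
  normalizer's positive feedback reliably empties the latent space
  (posterior collapse), after which no biology survives correction.

Two further implementation choices depart from the most literal reading of
the architecture and are deliberate:

* **Conditioning on the true label.** During training the decoder is
  conditioned on the true one-hot batch label, not the encoder's predicted
  probabilities. A continuous predicted code is an information
  side-channel: the encoder can smuggle arbitrary biology through tiny
  probability differences at negligible classification cost, the latent
  collapses, and correction (which decodes under hard one-hot codes)
  destroys the signal. With the classification loss trained, the predicted
  and true labels agree anyway.
* **Non-saturating adversarial surrogate.** The encoder's auxiliary term
  is optimized by minimizing the cross-entropy between the auxiliary's
  prediction and the uniform distribution, rather than maximizing its
  cross-entropy against the true label. The fixed point is identical (the
  auxiliary at chance level), but the surrogate is bounded: maximizing a
  cross-entropy rewards pushing the latent scale to infinity faster than
  the adversary can track, which we observed as KL divergences in the
  tens of thousands. This is the same trick GAN generators use. The
  auxiliary reads the posterior mean $\mu_q$, not the sampled $z$:
  reading the sample lets the encoder hide batch signal below the
  sampling noise while the deterministic mean retains it.

* **Polyak averaging.** With `ema_decay` set (the benchmark recipe uses
  0.97 per epoch), the returned encoder and decoder are exponential moving
  averages of the training trajectory, taken after the adversarial delay.
  Adversarial games orbit their equilibrium rather than land on it: the
  direction of the residual linearly decodable batch signal in $\mu_q$
  rotates across late epochs, so the time-averaged encoder carries far
  less of it than the final iterate, while the (stable) reconstruction is
  unaffected. This is the standard averaging trick for GAN training.

On the benchmark fixture the auxiliary is a *linear* (softmax) classifier.
A converged linear adversary removes exactly the linearly decodable batch
signal — the quantity a post-hoc probe measures — whereas a small
nonlinear adversary can sit at chance while a linear probe still reads a
leak it never noticed.

## Correction

After training, `correct_batches()` projects every cell onto the reference
batch (by default the most represented one; ties break lexicographically):
encode, draw $S$ latent samples by reparameterization, decode each under
the reference code, and average. The variance of the average scales as
$1/S$; the default $S = 10$ captures most of the reduction. The output has
the same cells, genes and order, with batch labels kept as metadata;
`project_to()` accepts any code, including the uniform "average batch" and
fractional interpolations (for two batches, the scalar 0.5 decodes halfway
between them). Averaging happens in the model's output space; negative
entries are not clipped by default so the projection constraint's effect on
them stays measurable (the CLI offers `--clip-negative`).

## The synthetic-data generator

`simulate_counts()` draws from the standard gamma-Poisson family: per-gene
base means from a Gamma distribution; a fraction `de_prob` of genes
differentially expressed between the two cell types with lognormal
multiplicative factors (direction up or down with equal probability,
recorded per gene in the ground truth); multiplicative per-gene batch
factors, lognormal around one, with the first batch as reference; lognormal
per-cell library sizes; Poisson counts; and logistic dropout on the
log-mean scale, so lowly expressed entries drop out more often. When a
`dropout_target` is given, the logistic midpoint is solved numerically so
the expected fraction of nonzero entries zeroed equals the target — the
`sim_config_dataset3()` and `sim_config_dataset4()` presets use 0.05 and
0.25, the two dropout regimes of the simulated benchmarks, on the same
411/989 cell-type and 500/900 batch composition.

With `normalize_library = TRUE` (default) per-cell gene means are rescaled
to sum to one, so the expected cell total equals the library size and cell
types compete for a fixed transcriptome share. This reproduces the
compositional behavior of library-normalized data — including the fact
that strong one-directional differential expression depresses the apparent
expression of every other gene. The "noiseless" test fixtures disable it,
because under compositional normalization perfect down-regulation recovery
is unattainable *for any method*; that is a property of normalized counts,
not of a test statistic.

What the generator does not emulate: over-dispersion beyond Poisson at
fixed mean (real data are negative-binomial), gene-gene correlation
modules, continuous differentiation trajectories, ambient RNA, doublets.
Passing tests on this generator therefore demonstrate the mechanics of
factorization, correction, and scoring — not performance on the full
complexity of real tissue.

## Evaluation framework

`evaluate_integration()` embeds (t-SNE for small data, UMAP for larger,
optional preliminary PCA), clusters (k-means with $k$ set to the number of
annotated types, or Louvain on a shared-nearest-neighbor graph), and
computes three metrics in two flavors each: adjusted Rand index of clusters
against cell types (purity) and against batches (mixing), average
silhouette width by cell type and by batch, and the local inverse Simpson
index — the effective number of labels in a Gaussian neighborhood whose
bandwidth is calibrated per cell to a fixed perplexity (default 30).
Because a single embedding/clustering seed can fail on perfectly good data
(k-means happily splits along an axis orthogonal to cell type), metrics are
computed under `n_seeds` seeds and per-metric *maxima* are reported; the
robustness protocol (`robust_evaluate()`) instead subsamples 80% of the
embedded cells twenty times and reports distribution summaries.

Per metric, a cell-type score and a batch-mixing score scaled to $[0,1]$
combine into a harmonic-mean F1: the ARI flavor uses the cell-type ARI
directly with mixing $1-\text{ARI}_{batch}$; the ASW flavor uses the raw
silhouettes, clamped, with mixing $1-\text{ASW}_{batch}$ (benchmark tables in the
integration literature print "1−B" values above one for slightly negative
batch silhouettes, which pins this convention); the LISI flavor normalizes
$(\text{LISI}_{batch}-1)/(K_b-1)$ and
$(K_{ct}-\text{LISI}_{ct})/(K_{ct}-1)$. The exact LISI normalization used in
reported integration benchmarks cannot be fully reverse-engineered from
their tables (reconstruction is off by up to ~0.09 on some cells); the
adopted formula is the natural one and is documented rather than tuned. `average_f1()` min-max
standardizes the three F1 scores across at least two compared methods and
averages them.

## Differential-expression benchmark

`de_benchmark()` scores how well a (corrected) dataset supports DEG
detection against simulation ground truth. Group labels are the true cell
types (supervised) or k-means clusters on a PCA embedding mapped to types
by majority overlap (unsupervised; when both clusters' majorities collapse
onto one type — one cluster mixing two cell types — the best one-to-one
assignment is used so the two-group test stays defined). On raw counts,
each gene is first clipped per group to its 0.02/0.98 quantiles; the test
is sensitive to outliers there. The per-gene test is a two-part
likelihood-ratio test for bimodal single-cell expression: a detection rate
(zero versus nonzero) and a Gaussian positive component with variance
pooled under the alternative, giving $2(\ell_{alt}-\ell_{null})$ against
$\chi^2_2$. Genes all-zero in both groups get $p = 1$. Benjamini–Hochberg
correction at 0.05 is applied before the log-fold-change filter (the
correction choice is configurable; the filter is the primary guard against
the test's noisy calls). Base-2 log fold changes use the difference of
means over $\ln 2$ on log-normalized values and
$\log_2((m_1+1)/(m_2+1))$ on raw counts.

Up- and down-regulated calls at each threshold of a grid (0 to 1 in steps
of 0.05) are scored by F1 against the true DEG sets restricted to
$|{\log_2\text{FC}}| >$ threshold; both sets empty counts as agreement
(F1 = 1), exactly one empty as disagreement (0). The F1-versus-threshold
curve is integrated by trapezoids and divided by the grid range, so a
constant-perfect curve has AUC 1. The HVG variant restricts everything to
the top 2,000 genes by log-expression variance.

## The benchmark fixture and its recipe

`run_strong_batch_benchmark()` freezes the package's reference experiment:
1,500 cells (batches 600/900, cell types 450/1,050), 500 genes, 30% DE
genes at ~4-fold between clearly distinct cell types, and multiplicative
batch factors of lognormal scale 0.8 — strong in the operative sense that
a logistic probe on the raw data identifies the batch essentially
perfectly. Training uses a 4-dimensional latent space behind 64/64 hidden
layers, a linear auxiliary, adversaries delayed 50 of 225 epochs so the
autoencoder settles first, minibatches of 128, Adam at $3\times10^{-4}$
($5\times10^{-3}$ for the auxiliary), and weights
$\alpha=0.1, \rho=0.5, \beta=0.01, \mu=0.02, \delta=0.01, \gamma=0.3$ —
reconstruction-dominant, because after normalization the weights are the
effective relative importances. These sizes keep a full train-correct-
evaluate cycle within a few minutes on one CPU while leaving the
phenomena of interest (probe accuracy near the majority rate, batch LISI
near 2, cell-type ARI preserved, under 5% negative entries) comfortably
measurable; they are the package's reference settings, not a claim of
optimality at other scales.

```{r example}
bench <- run_strong_batch_benchmark(seed = 1)
probe_accuracy(aif_encode(bench$fit$model, bench$dataset$matrix)$mu,
               bench$dataset$batch)     # ~ majority rate: batch removed
ev <- evaluate_integration(bench$corrected$matrix, bench$dataset$batch,
                           bench$dataset$cell_type,
                           eval_protocol(n_seeds = 5))
tidy(ev)
autoplot(bench$fit$report)
```

## Degenerate inputs and edge rules

* Cosine similarity of a zero-norm vector is defined as 0.
* Cross-entropies clamp probabilities at $10^{-7}$; losses stay finite at
  saturated predictions and gradients pass through (the straight-through
  convention of every deep-learning framework).
* Tied distances in the LISI kernel are handled by shifting distances by
  their minimum (the normalized weights are invariant), so a perfectly
  symmetric neighborhood yields the uniform kernel rather than underflow.
* A single-batch dataset is rejected at training time: there is nothing to
  factor out.
* Reference-batch ties break to the lexicographically smallest label.
* The median-count log-normalization errors on zero-total cells, naming
  them; per-cell scale factors are stored so the transform is invertible.
* Raw-space integrality is enforced for constructed datasets but not on
  the read path: corrected data live in raw space yet are continuous and
  occasionally negative by design.

## Known limitations

Training is an adversarial game: equilibria are approximate, the residual
linear leak in the latent space fluctuates over epochs, and hyperparameters
that work at one data scale need re-tuning at another (per-dataset tuning
is the norm for this model family). The Gaussian positive component of
the LRT is an approximation for counts; its null calibration is verified by
simulation in the test suite rather than assumed. The evaluation metrics
are computed in an embedded space and inherit the embedding's biases — the
max-over-seeds protocol mitigates, but does not remove, them.
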