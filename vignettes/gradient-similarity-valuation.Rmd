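---
title: "Valuing samples by gradient similarity: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing samples by gradient similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dvgs)
```

## The valuation model

Data valuation asks: given a pool of *source* samples and a *target*
dataset that defines the prediction task, how useful is each source
sample? The premise of gradient-similarity valuation is that a source
sample whose loss surface resembles the target's loss surface will help
optimization toward the target task, and one whose loss surface opposes
it (a mislabeled sample, say) will hurt. Comparing full loss surfaces is
intractable, so the method compares *gradients at the parameter values an
optimizer actually visits*: it runs plain SGD on the target set and, at
recorded iterations, computes the cosine similarity between each source
sample's loss gradient and the current target mini-batch gradient. The
sample's value is the mean recorded similarity.

Cosine similarity is used deliberately: it is bounded in [−1, 1], easy to
interpret, and ignores gradient magnitude. Magnitudes differ sharply
between early and late training, and between low- and high-loss samples,
so a magnitude-sensitive criterion would conflate training stage with
sample quality. A consequence worth keeping in mind is that values are
*relative, rank-ordered* quantities: they satisfy none of the Shapley
equity axioms, and their absolute scale should not be over-interpreted.
The evaluation statistics in this package (`corruptionAUROC()`,
`noiseSpearman()`) are correspondingly rank-based.

Two similarity records are affected by class imbalance in classification
targets: a majority class dominates the target batch gradient and biases
values toward that class. `dvgsConfig(classBalance = TRUE)` therefore
weights per-sample losses inversely to class frequency when computing
target gradients. The weights are computed once from the full target set
rather than per batch: at realistic batch sizes (tens of samples),
per-batch frequencies are noisy and would inject variance into the
reference direction.

## Algorithmic details and conventions

- **Recording order.** Similarities at iteration i are recorded *before*
  the parameter update of iteration i, so the recorded trajectory is the
  pure SGD trajectory; recording never perturbs optimization (this is a
  tested invariant).
- **Period T.** With `similarityPeriod = T`, similarities are recorded at
  iterations T, 2T, ..., cutting the dominant cost (per-source-sample
  gradients) by a factor of T. Values are averaged over *recorded*
  iterations only, keeping them a mean of similarities regardless of T.
  On the synthetic classification task the value rankings at T = 2..5
  agree with T = 1 at Spearman ≥ 0.98, so moderate thinning is safe.
- **Zero gradients.** Cosine similarity with a zero-norm vector is
  defined as 0: a vanished gradient carries no directional information.
- **Mini-batching.** Target batches are drawn without replacement within
  an epoch and reshuffled each epoch, all under the run seed.
- **Multi-run aggregation.** Each run r uses seed `baseSeed + r − 1` for
  both initialization and batch order; values pool across runs weighted
  by recorded-iteration counts (`aggregateRuns()`), equaling the grand
  mean over all recorded similarities. Multiple runs explore multiple
  optima and reduce the variance of the final ranking.
- **Divergence.** A non-finite target loss aborts the run with the
  iteration number; no values are silently returned.
- **Optimizer.** Plain constant-rate SGD. Momentum or adaptive methods
  would change which parameter regions are visited; they are deliberately
  out of scope to keep the recorded trajectory interpretable.

## The two gradient paths

Per-sample gradients are the computational bottleneck. The package has
two mathematically identical implementations: an explicit loop
(`perSampleGradients()`, one backward pass per sample, materializing the
gradient matrix) and a vectorized path that exploits the structure of
fully-connected layers — the per-sample weight gradient is the outer
product of the layer input and the backpropagated delta, so dot products
with a reference gradient and per-sample norms reduce to dense matrix
products without ever forming per-sample gradients. The loop is the
reference; the fast path must agree with it to 1e−5 (in practice it
agrees to ~1e−15) and both are exposed via
`gradientSimilarities(method=)`. All analytic gradients are additionally
checked against central finite differences.

## Architectures and their defaults

The two built-in models mirror common practice for small tabular and
expression data: a 2-layer MLP classifier (softmax cross-entropy, two
output units even for binary tasks so multi-class problems are handled
uniformly) and an autoencoder with two weight layers in each of the
encoder and decoder and a 32-dimensional latent space, trained on
feature-wise mean squared error. Hidden width (MLP default 100), ReLU
activations, and the autoencoder's hidden width (geometric mean of input
and latent dimensions) are package choices — standard, gradient-friendly
defaults for this model scale — and are configurable. Initialization is
Glorot-uniform under an explicit seed; construction is bit-reproducible.

## Baselines

- `randomValues()` draws Uniform(0, 1) values — the null model whose
  corruption AUROC centers at 0.5 and noise Spearman at 0.
- `looValues()` scores each sample by the target-performance drop when it
  is removed and the learner refit; the sign convention (positive =
  valuable) matches the gradient-similarity orientation so all methods
  share one evaluation path. Degenerate refits yield `NA` for that sample
  and the run continues.
- `tmcShapley()` estimates Data Shapley values by truncated Monte-Carlo
  permutation sampling: marginal contributions along random permutations,
  truncated once the running score is within tolerance of the full-data
  score (default 1% of |full score|), stopping early when values
  stabilize (< 0.001 change over 10 permutations). The empty-set score is
  the learner's uninformed prediction (global mean / uniform
  probabilities) — a convention this package declares, since the
  coalition game needs a defined v(∅). `exactShapley()` enumerates all
  permutations (n ≤ 8) and anchors the estimator's tests;
  `shapleyConfig(exhaustive = TRUE)` makes the estimator itself enumerate
  exhaustively, which with truncation 0 reproduces exact values.

## Corruption generators and their statistics

`flipLabels()` relabels a round(proportion · n) subset chosen uniformly
without replacement; the new label is drawn from the *other* classes, so
every flagged sample is genuinely wrong. `addFeatureNoise()` draws a
per-sample rate φ_i ~ Uniform(low, high) and adds independent
Normal(0, sd = φ_i) noise to every feature. The second argument of the
noise law is interpreted as a *standard deviation*; dispersion is then
monotone in φ either way, and standard deviation is the more
interpretable scale. The default range Uniform(0, 1) is calibrated to
standardized features: at the top of the range the noise is comparable in
magnitude to the signal. Ground truth (mask, rates) is always returned
alongside the corrupted data, and uncorrupted entries are bitwise
untouched.

Evaluation uses AUROC(c, −ν) (mid-rank Mann–Whitney, tie-safe) for masks
and Spearman(φ, −ν) for rates — the sign flips encode the expectation
that corrupted or noisy samples receive *low* values.

## Filter-and-retrain

`filterAndRetrain()` removes the floor(q · n) lowest- (or highest-)
valued samples at each fraction q, refits a learner, and scores a
held-out test set. Ties at the cutoff are broken by a seeded random
order so the removed count is exact. Classification curves use AUROC;
reconstruction curves use R² of the reconstruction on the test set. Two
practical notes from the synthetic experiments: the comparison is only
meaningful when each refit is trained to (near) convergence — an
undertrained model is data-hungry and more data beats cleaner data — and
fraction 0 is by construction identical in both directions (the kept-row
set is canonicalized, so curve pairs share their baseline).

## Replicate concordance (APC)

For replicate-structured expression data, `apc()` computes each
perturbation group's mean pairwise Pearson correlation across its
replicate profiles — the established L1000 sample-quality heuristic, with
high quality conventionally meaning APC > 0.5 (`apcPartition()`, strict
inequality). Groups with one replicate are `NA`; pairs involving a
constant profile have undefined correlation and are dropped from the mean
(and counted), rather than imputed as 0. When replicate counts differ
between groups, the mean is unweighted within each group — each group
summarizes its own pairs.

## What the synthetic generators emulate — and what they do not

`makeBlobs()` produces standardized class-conditional Gaussians with all
pairwise class-mean distances equal to `separation`, a stand-in for
separable tabular or featurized-image data. `makeReplicateExpression()`
emulates L1000-style structure: group signatures on a low-dimensional
latent manifold (default 32 factors across 978 genes — real signatures
are strongly gene-correlated, and an independent-gene signal would leave
an autoencoder nothing to learn), per-replicate noise with
heterogeneous standard deviations, and level-5-style signatures as
per-group replicate means (the real pipeline's MODZ weighting is
deliberately simplified away). Defaults: signal sd 1 per gene, noise sd
Uniform(0.1, 2) per replicate — a range that spans clearly-concordant to
clearly-discordant replicate groups around the APC = 0.5 threshold.

These generators support mechanism tests, not effect-size claims: they
contain no batch effects, no dose/time/cell-line covariates, no
structured artifacts, and their noise is exactly the Gaussian model the
statistics assume. Passing tests show the algorithms recover *this*
structure; real-data corruption is messier, and real effect sizes (e.g.
how much filtering improves a model) will differ.

## Problem sizes and numerical choices in the shipped experiments

The packaged experiments use 1000 source / 400 target samples with 20%
label corruption for the classification studies (the reference sizes for
tabular benchmarks), SGD with rate 0.05, batch 50, and 600 iterations —
enough for the 2-layer MLP to reach its stable regime on the blob task.
The unsupervised study values 500 level-5 signatures against a 200-
signature target with a 100-signature held-out test set, using full-
target batches (size 200), rate 0.15, 1600 iterations with period 8, and
two pooled runs: full batches stabilize the reference direction, and the
longer, slower schedule keeps the trajectory in the informative
mid-training regime — once the autoencoder begins memorizing the target,
gradient alignment stops discriminating noise (a behavior visible in the
schedule sweeps, and the reason pretraining is off by default for this
task). Filter-and-retrain refits train 400 epochs at rate 0.5 so that
each refit is near its asymptote rather than data-limited.

## Known limitations

- Values are trajectory averages; with few recorded iterations or a
  single run they can be noisy, and multi-run pooling is recommended.
- High values mean "gradient-similar to the target", which is not
  identical to "most useful": redundant or target-like samples rank
  high, and the method is known to be weaker at identifying the *most*
  valuable data than retraining-based baselines. Treat the top of the
  ranking with more caution than the bottom.
- The unsupervised mechanism's discrimination depends on where the
  optimizer is: too early, gradients are dominated by shared
  initialization error; too late, by target memorization. The shipped
  schedule targets the informative window for the shipped problem sizes;
  substantially different data scales will need their own schedule.
- Detecting noisy samples is not the same as benefiting from their
  removal. In the shipped unsupervised study (500 signatures, zero-mean
  Gaussian replicate noise), values track the true noise level well
  (Spearman ~ 0.5), yet removing the lowest-valued 20% does *not* improve
  held-out reconstruction R² — and neither does removing the 20% truly
  noisiest by the generator's own ground truth. Unbiased Gaussian noise
  largely averages out during training, so at a few hundred samples the
  cost of discarding 20% of the data outweighs the benefit; gains from
  filtering should be expected only when low-quality samples are
  structurally biased or the sample budget is large.
- The fully-connected architectures are the scope; convolutional or
  pretrained feature extractors are not provided.
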