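---
title: "Multinomial convolutions: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multinomial convolutions: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifconv)
```

## The model

`motifconv` fits a regression from DNA sequence to a real-valued activity
readout — the setting of massively parallel reporter assays (MPRA), where
thousands of candidate enhancer sequences each receive one activity
estimate. The architecture is a convolutional network whose first layer is
constrained to be directly interpretable as sequence motifs.

Each of the $F$ convolution kernels is parameterized by a free real matrix
$X \in \mathbb{R}^{L \times 4}$ (positions by bases A, C, G, T) that is
mapped, at every forward pass, through a temperature softmax

$$T_{i,j} = \frac{e^{\alpha X_{i,j}}}{\sum_{j'} e^{\alpha X_{i,j'}}},$$

so every row of $T$ is a multinomial distribution over the four bases:
$T$ *is* a position weight matrix, with no post hoc interpretation step.
The convolution computes, for every length-$L$ window $s$ of the one-hot
encoded input,

$$\mathrm{LLR}(s) = \sum_{i=0}^{L-1} \sum_{j=0}^{3}
  \ln\!\frac{T_{i,j}}{B_j}\, s_{i,j},$$

the log of the likelihood of generating $s$ from $T$ over generating it
from a background base composition $B$ (default human genomic:
A 0.295, C 0.205, G 0.205, T 0.295). Both the forward strand and the
reverse complement are scanned with shared kernels; the activated LLR
values of all $2(N-L+1)$ windows are pooled jointly into one value per
filter, followed by dropout and a fully connected head. With the default
single-node head there is a one-to-one pairing between kernels and dense
weights, so the weight sign classifies each motif as a candidate activator
(positive) or repressor (negative).

Training minimizes mean squared error plus an L2 penalty on convolution
and dense weights, with Adam, glorot-uniform initialization, shuffled
minibatches and early stopping on validation MSE (best weights restored).
Because $T$ is re-derived from $X$ inside every forward pass, gradients
flow through the softmax; the useful identity
$\partial \ln T_{i,j} / \partial X_{i,j} = \alpha\,(1 - T_{i,j})$ means
that reducing the loss pushes used positions toward sharper distributions,
while the background denominator discourages kernels that merely mimic
base composition.

## Parameters that matter

* `n_filters` (default 512) and `filter_length` (default 12 bp): the
  cross-validated optimum of the original liver-enhancer study; at desk
  scale far fewer filters (e.g. 8) recover planted motifs well.
* `alpha` (default 120, dimensionless): softmax temperature. The study
  searched 100–140 but never printed the winning value, so this package
  defaults to the midpoint. Large `alpha` makes kernels nearly
  deterministic; `ln T` is therefore always computed as
  $\alpha X - \mathrm{logsumexp}(\alpha X)$ per row, never as
  `log(softmax(...))`, which would underflow. `alpha` is a fixed
  hyperparameter by default; `alpha_trainable = TRUE` optimizes it jointly,
  since the original description is ambiguous about whether it was trained.
* `activation` (relu), `pooling` (max, jointly over both strands),
  `dropout_rate` (0.4), `batch_size` (64), `learning_rate` (0.001),
  `l2_factor` (0.001): the published optimal architecture.
* `early_stopping_patience` (10 epochs) and `max_epochs` (100): the source
  only states that early stopping was used; these values are this
  package's choices, and the effective epoch count is governed by the
  validation curve.

Cross-validation follows the published protocol: ids are shuffled once,
the k test blocks partition the data (10% each at k = 10), one tenth of
each remainder is validation (9% overall) and the rest training (81%);
the metric is the mean held-out Spearman correlation over folds.

## Design choices where the source was open

* **Strand merge.** The two strand scans could be pooled jointly or
  pooled separately and concatenated. Joint pooling is used because it
  preserves the one-to-one kernel/dense-weight pairing and makes
  predictions exactly strand-symmetric: a sequence and its reverse
  complement score identically.
* **Activation before pooling**, matching the stated processing order of
  the convolution outputs.
* **No convolution bias.** A bias would break the likelihood-ratio
  reading of the scores; bias terms exist only in the dense head.
* **Initialization.** Raw kernel weights start at glorot-uniform scale
  divided by `alpha`, so the softmax logits $\alpha X$ start at glorot
  magnitude. An unscaled glorot draw at $\alpha \approx 120$ saturates
  the softmax; combined with ReLU and max pooling every pooled feature is
  then exactly zero and no gradient flows (observed empirically at small
  filter counts). Dense weights use plain glorot-uniform; biases start at
  zero and are excluded from the L2 penalty.
* **Ambiguous bases.** `N` becomes an all-zero one-hot row, contributing
  zero to every LLR term — likelihood-ratio-neutral, the least informative
  convention.
* **Regularization type.** The source searched regularization types
  without naming the winner; L2 with the printed factor 0.001 is used.
* **Two-layer head.** Width 16 with ReLU (unstated in the source); with
  two dense layers the per-filter role is no longer identifiable, so
  extracted motifs come back `unassigned`.
* **Validation sets** are nested per fold inside the 90% remainder, which
  is what makes the printed 81/9/10 proportions exact; they may overlap
  across folds, test sets never do.
* **Tie-breaks.** Spearman uses average ranks; grid-search ties prefer
  the smaller model, then grid order; max pooling breaks ties by first
  window index (deterministic).

## The synthetic world

`simulate_mpra()` emulates the structure, not the biology, of an MPRA
dataset: fixed-length sequences drawn i.i.d. per base from the background;
per motif and sequence, with probability `plant_probability` (default
0.5), a site sampled from the motif's distribution is inserted at a
uniform non-overlapping position on a random strand; activity is

$$y = \beta_0 + \sum_m w_m \cdot \max_{\text{strand, position}}
\mathrm{LLR}_m + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$

with $\sigma$ defaulting to one quarter of the noiseless activity standard
deviation. Defaults mirror the real study's scale at desk size: 2,000
sequences of 150 bp (the study had 2,440 sequences), one planted activator
(weight +1) and one planted repressor (weight −1), both sharp 12-bp
consensus PWMs. Because activity is generated by the model's own
max-pooled LLR mechanism, parameter recovery is well-posed — which is
precisely what the generator is for.

What a green recovery test does **not** establish: performance on real
MPRA data, where activity is not a linear function of two motifs' best
hits, motif grammar and chromatin context matter, and measurement noise is
not Gaussian or homoscedastic. The generator also does not simulate
barcode-level counts, GC bias, or overlapping/cooperative sites
(placement is non-overlapping by rejection sampling, capped at 100
retries).

## Numerical notes and degenerate inputs

* Row-stochasticity of kernels holds to 1e-6 by construction; at
  $\alpha \gtrsim 100$ individual probabilities can underflow to exact 0
  in double precision while `log_probs` stays finite — log space is the
  authoritative representation.
* Likelihood conservation ($\sum_w e^{\mathrm{LLR}(w)} P(w\mid B) = 1$)
  is verified by brute-force enumeration for small $L$ in the test suite.
* Scanning uses valid windows only (`N - L + 1` scores, 0-based half-open
  coordinates); sequences shorter than the kernel are an error, as are
  alphabet violations (reported with position and offending character).
* ICP (information content per position) renormalizes rows by their sums,
  uses log base 2, and adopts $0 \cdot \log 0 = 0$; an all-zero row is a
  degenerate-motif error.
* MEME export prints six decimals; import renormalizes rows whose sums
  deviate by at most 1e-3 and rejects anything worse with a line number.
* All randomness (init, shuffling, dropout, folds, simulation) flows from
  explicit integer seeds; per-fold seeds are derived from the master seed
  and fold index. Training runs restore the caller's RNG state.

## Limitations

The training engine is plain R: fine for the package's contract (CPU,
thousands of sequences, hundreds of filters) but not for genome-scale
corpora. Motif-database matching (e.g. Tomtom) is deliberately out of
scope — export motifs with `write_meme()` and run external tools; novel
versus known calls therefore depend on that external step. The conventional
CNN baseline reproduces the published comparator architecture but shares
the engine's scale limits, and the headline benchmark numbers of the
original study are not reproducible offline, so they are documented rather
than asserted.
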