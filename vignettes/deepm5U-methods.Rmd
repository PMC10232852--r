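---
title: "deepm5U: models, training protocol and interpretation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deepm5U: models, training protocol and interpretation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the data model,
the five classifier architectures and their training regime, the three
interpretation procedures, the synthetic benchmark that stands in for
experimental m⁵U data, and the numerical and design decisions taken where
the problem left the choice open.

## The classification problem

RNA 5-methyluridine (m⁵U) sites are distributed as fixed-length 41-nt
windows over `{A,C,G,U}` with the queried uridine at the center (1-based
position 21); unmodified uridine windows from the same transcripts form the
negative class.  The task is binary classification of a window, and — at
least as important in practice — attribution of that classification back to
sequence positions, since the scientific question is *which* flanking
context marks a methylatable uridine.

`read_labeled_sequences()` accepts FASTA or one-sequence-per-line text, one
file per class.  `T` is accepted as an alias of `U` because deposited site
lists frequently come in DNA alphabet from genomic coordinates.  Window
length and alphabet violations are hard errors (or droppable with
`skip_invalid`); a non-U center is deliberately only a warning so that the
toolkit can be reused for other single-nucleotide marks where the center
base differs.  Sequences occurring in both classes are surfaced in a
`duplicates` attribute without second-guessing the caller's intent.

Windows are one-hot encoded in the fixed channel order A, C, G, U
(A = (1,0,0,0) … U = (0,0,0,1)) into an `N × 41 × 4` array.  Encoding is a
strict bijection on valid sequences and the test suite asserts the
round-trip property on random windows.

## Architectures

Five stacks over the 41 × 4 input are provided by `architecture_spec()`:

| name | body |
| --- | --- |
| `CNN` | conv(250, k11) ×2 → maxpool(10, s10) |
| `BiLSTM` | bilstm(256, sequences) → bilstm(256) |
| `BiGRU` | bigru(256) |
| `CNN_BiLSTM` | conv(250, k7) ×2 → maxpool(4, s4) → bilstm(64) |
| `CNN_BiGRU` | conv(250, k11) → maxpool(10, s10) → bigru(256) |

every one followed by dense(256) → dropout(0.2) → ReLU → output(1, sigmoid).
Convolutions are *valid* (no padding), stride 1, with inline ReLU; the time
axis therefore contracts as `floor((L − k)/s) + 1` per layer
(`conv_output_length()`), giving the traces 41→31→21→pool→2 for `CNN` and
41→35→29→pool→7 for `CNN_BiLSTM`.  `shape_trace()` computes this symbolic
trace without touching the engine, and the tests require the built model to
reproduce it layer for layer.

Two conventions had to be fixed where the stack descriptions are ambiguous:

* **Recurrent "units" are per direction.**  A bidirectional layer with 256
  units outputs 512 features (the concatenation of both directions' final
  hidden states; with `return_sequences`, a 41 × 512 sequence).  This is the
  convention of the mainstream deep-learning frameworks.
* **Dense input.**  After convolution/pooling the feature map is flattened
  time-major (position 1's channels, then position 2's, …); after a final
  recurrent layer the concatenated last hidden states are used directly.

### The engine

No deep-learning framework is part of the package's dependency stack; the
layers are implemented directly in Rcpp/RcppArmadillo (`src/nn.cpp`),
single precision, with BLAS GEMM doing the heavy lifting (convolution via
im2col).  Gate equations are the standard ones: LSTM input/forget/candidate/
output gates with tanh candidate and cell, and the *classic* GRU
formulation in which the candidate state uses the reset-gated previous
hidden state, `h̃_t = tanh(W_hx x_t + W_hh (r_t ∘ h_{t−1}) + b_h)`,
`h_t = (1 − z_t) ∘ h̃_t + z_t ∘ h_{t−1}` (not the `reset_after` variant).
Initialisation is Glorot-uniform with the LSTM forget-gate bias set to 1;
Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-7.  All randomness — initialisation,
epoch shuffling, dropout — flows from one Mersenne-Twister generator seeded
per call, so training is bit-reproducible on a given BLAS.

Correctness is enforced by two independent oracles in the test suite: a
pure-R double-precision forward pass re-implementing every layer with plain
loops (agreement to ~1e-5, the single-precision limit), and central finite
differences over randomly sampled weights in every parameter matrix of both
recurrent variants (agreement to 5%, the fp32 differencing limit).

## Training protocol

`training_config()` encodes the regime: Adam, learning rate 0.001, exactly
20 epochs (no early stopping, no schedule), batch 64, binary cross-entropy,
5 repeats.  Data handling is stratified throughout: `three_way_split()`
produces 70/10/20 train/validation/test with per-class counts within one
record of `round(frac × n)`, shuffled and fully determined by its seed.

`train_ensemble()` repeats training five times and deploys the *mean* of
the member probabilities (`predict_proba()`).  The test partition is fixed
once; each member re-shuffles the remaining 80% pool into its own
train/validation split under `seed + member` and re-initialises its
weights.  Re-shuffling per repeat (rather than only re-initialising) was
chosen because the protocol relies on shuffling for member diversity; the
fixed test set guarantees that no member ever sees a test record in its
training or validation stream, which the tests assert by id.

Classification uses threshold 0.5 with ties going to the positive class.
Class weighting is available (`class_weighting = "balanced"`) but off by
default — imbalanced benchmarks at 1:10 are evaluated as-is, with the
metric layer (below) handling the degenerate cases weighting would mask.

## Metrics

`confusion()` counts the 2×2 table with label 1 positive; accuracy,
precision, recall, F-value `2TP/(2TP+FP+FN)` and MCC follow the standard
formulas.  Degenerate denominators (e.g. precision with no positive calls,
MCC with an empty margin) return 0 with a warning rather than `NaN`, so
evaluation pipelines over imbalanced subsets always produce a full report.
ROC and PR curves sweep thresholds over the unique scores in descending
order with ties grouped; the ROC is anchored at (0,0) and (1,1) and ties
produce diagonal segments.  auROC is the trapezoidal area (equal to the
concordance probability with ties counted half, which the tests verify by
exhaustive pair enumeration); auPR uses step interpolation
(`Σ ΔR · P`), avoiding the optimistic bias of trapezoidal PR areas.  One
worked numeric example pins the formulas: a classifier that calls 36 of 41
true sites correctly has ACC = 36/41 = 87.80%.

## Interpretation

### Layer-wise UMAP

`extract_layer_output()` truncates the forward pass at any layer (by name
or index; 0 is the one-hot input) and flattens multi-dimensional outputs
time-major, one row per sample.  `umap_project()` embeds the activation
matrix in 2-D via the bundled `umap-learn` runner (n_neighbors 15, min_dist
0.1 by default, `random_state` fixed by the seed), and
`class_separation()` quantifies what the published figures show visually —
two point clouds separating by label — as the mean silhouette width of the
embedding under the class labels.  On a well-trained model the silhouette
of the last hidden layer exceeds that of the input layer; the acceptance
suite checks exactly this monotonicity.  Conv/pool layers are fully
flattened before projection; per-axis reductions are possible upstream of
`umap_project()` but no fidelity to any particular compression scheme is
claimed.

### Shapley attribution

`shapley_values()` attributes `f(x)` to feature groups against a background
reference set.  The value of a coalition `S` is the mean model output over
composites that take `S`'s coordinates from `x` and the rest from a
background sample (the interventional expectation).  Two estimators share
this value function:

* **exact** — all `2^M` coalition values are evaluated (feasible to M = 8)
  and combined by averaging marginal contributions over all `M!` orderings;
  the tests verify agreement with the independent factorial-weighted subset
  formula to 1e-6.
* **sampling** — Castro-style permutation sampling with `nsim` seeded
  random orderings, each evaluated as one batched forward pass.  Because
  each permutation's marginals telescope, the additivity identity
  `f(x) = φ₀ + Σ φᵢ` holds *exactly* under both estimators, with
  `φ₀` the mean output over the background.

`shap_attributions()` applies this to sequences with one group per
position (a position's four channels travel together, so composites remain
valid one-hot windows) and writes the per-position value into the observed
base's channel of a 41 × 4 matrix.  The background defaults to a seeded
subsample of training sequences; because every background window also has
U at position 21, the center is a null player and receives exactly zero —
the attribution analogue of "the constant center cannot carry signal".
Ensembles are explained as their averaged-probability function, since that
is the deployed predictor.

For logo display, `normalize_and_accumulate()` rescales each sequence's
matrix by `0.25 / max|φ|` — per sequence, not globally, because the bound
"summed values in [−1, 1]" is a per-sequence statement — then sums the
scaled values by position and observed base across sequences.  Scaling
never changes a sign; sequences whose scaled sum still escapes [−1, 1]
(possible when many positions carry weight) are flagged rather than
clipped.

### Saturation mutagenesis

`saturation_mutants()` enumerates the 41 × 3 = 123 single-base mutants in
position-major, A/C/G/U order; `effect_scores()` predicts wild type and all
mutants in a single batch and reports `Δp = p(mutant) − p(wild type)`
(positive = pushes toward m⁵U), wild-type cells pinned to 0.  The center
*is* mutated — the procedure substitutes every position — and downstream
analyses may mask it when the center U is definitional.  Observed effect
magnitudes are reported, not thresholded: how small the deltas of
correctly-classified sites are is a property of the trained model and
dataset, not a package constant.

## The synthetic benchmark

`generate_dataset()` emulates the statistical structure of the m⁵U
benchmarks without their data: 41-nt windows, U fixed at position 21 in
*both* classes, negatives i.i.d. from a background composition (uniform by
default), and positives identical to negatives except that each configured
motif is written at its position with probability `plant_prob`.  The
default motifs are the two determinants reported for m⁵U context — `GGU` at
18–20 and `CXAXCCC` at 23–29 (`X` = wildcard left to background, so the
determined positions are 18–20, 23, 25, 27–29).  Motifs may neither overlap
each other nor the center.

Default `plant_prob` is 0.9 rather than 1: with full penetrance the task
is trivially separable and the FP/FN code paths of the metric layer would
never be exercised; at 0.9 roughly a tenth of positives are
indistinguishable from negatives, which caps attainable accuracy near 95%
and produces non-degenerate confusion tables.  A `biased_background()`
preset raises upstream G and downstream C frequencies for logo-rendering
demonstrations of the composition bias seen around real sites.

What the simulator deliberately does *not* model: read-level sequencing
noise, transcript structure (the exonic/intronic "full transcript" versus
"mature mRNA" distinction), genomic background composition, or motif
position jitter.  Tests passing on this benchmark therefore demonstrate
that the pipeline recovers a planted, position-locked signal — a necessary
condition, not evidence about performance on experimental data.

## Problem sizes and numerical choices

The end-to-end study run by the acceptance suite and by
`scripts/acceptance.R` uses 2,000 + 2,000 windows at `plant_prob` 0.9 with
the full published regime (CNN-BiLSTM, 5 members, 20 epochs).  The
interpretation stage explains 24 held-out motif-carrying positives with a
10-sequence background and 8 sampling permutations — sizes chosen so the
accumulated-logo statistics are stable while each explanation stays a few
thousand forward passes; mutagenesis scores 20 held-out positives; the
UMAP comparison embeds the full 800-window test set.  For interactive use
on real data, larger backgrounds (~100) and more permutations sharpen
individual attributions; the accumulation over sequences is what makes the
small per-sequence budgets sufficient here.

Other numerical details, for completeness: probabilities are clipped to
`[1e-7, 1 − 1e-7]` inside the cross-entropy; max-pooling breaks ties toward
the earlier position; dropout uses inverted scaling at train time and is
the identity at inference; the last partial minibatch of an epoch is
trained on (not dropped); single-precision arithmetic bounds
forward-reference agreement near 1e-5 relative.

## Known limitations

* The engine is CPU-only and single-threaded beyond BLAS; it is sized for
  41-nt windows and the published widths, not for genome-scale inputs.
* `umap_project()` shells out to Python's `umap-learn`; without it the
  projection (only) is unavailable.
* Exact Shapley is limited to 8 feature groups; full 41-position windows
  always use the sampling estimator, whose per-position variance shrinks
  only as `1/√nsim`.
* Grid search trains one model per candidate with a user-supplied (usually
  reduced) epoch budget; it selects by validation accuracy with a
  fewer-parameters tie-break, and does not cross-validate.
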