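---
title: "Scoring miRNA target-site binding from complementarity matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA target-site binding from complementarity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsite)
```

## The problem

miRNAs repress messenger RNAs by guiding Argonaute proteins to short target
sites. The classical heuristic calls a site functional when the target
carries a perfect Watson–Crick complement of the miRNA "seed" (here the 2–7
hexamer, 1-based from the 5' end). Unbiased chimeric-read experiments,
however, attribute roughly 60% of observed miRNA:target duplexes to
non-canonical pairing, including ~18% that bind only through the miRNA 3'
end. `mirsite` implements a sequence-agnostic alternative: the pair is
reduced to its pairing geometry and scored by a small neural network, so
canonical and non-canonical sites compete on equal footing.

## The binding-matrix encoding

A miRNA is standardized to exactly 20 nt (5'-anchored truncation, 3' `N`
padding) and a target site to a 50-nt window (re-centered as
`[c - 25, c + 25)` with `c = floor((start + end) / 2)` in 0-based half-open
coordinates; windows truncated by a contig edge are `N`-padded rather than
discarded). The pair becomes a 20 × 50 matrix whose entry *(i, j)* is 1
exactly when miRNA position *i* and target position *j* form an A:U or G:C
pair. Three conventions deserve note:

* **Orientation.** Rows index the miRNA, columns the target, both read
  5'→3' as given, with no strand reversal inside the encoder. The
  transposed convention is equally defensible; we fix one, document it, and
  a caller preferring 50 × 20 may transpose the matrix.
* **Wobble pairs.** G:U pairs are *not* encoded — the representation is
  strictly Watson–Crick. Anything involving `N` scores 0.
* **T vs U.** Inputs are case-folded and `T` is mapped to `U` everywhere,
  because target windows typically come from DNA references.

A perfectly complementary duplex therefore appears as an anti-diagonal run
of 1s; a seed match is a 6-long such run against rows 2–7. Random
backgrounds produce isolated 1s at rate ~¼ per cell, so the signal is a
local geometric pattern — exactly what small convolutional filters detect.

## Scorers

`build_cnn()` assembles the convolutional scorer: six blocks of
(5 × 5 convolution, leaky ReLU, batch normalization, 2 × 2 max pooling
after blocks 2, 4 and 6, dropout), two dense blocks, and a single sigmoid
output unit interpreted as the binding probability. `build_resnet()`
assembles a residual alternative whose first operation is the first
residual stage's own 3 × 3 convolution: on a 20 × 50 input an ImageNet-style
7 × 7 stem plus pooling would collapse the grid below what later blocks
need, so there is no stem convolution and no stem pooling; stages are
separated by 2 × 2 max pooling and a global average pool feeds the sigmoid
unit.

Two presets are provided:

* **full** — channel widths 32/32/64/64/128/128, dense 128/64, dropout 0.3,
  Adam at learning rate 0.00152, 10 epochs, batch size 32. This mirrors the
  published full-scale recipe and is intended for real training runs.
* **desk** — widths 8/8/16/16/32/32, dense 32/16, dropout 0.1, learning
  rate 0.003, 6 epochs, batch size 128. This is the package's CI-scale
  preset: the architecture shape is identical, but the capacity and
  schedule are sized so that a training run on a few thousand pairs
  finishes in minutes on one CPU. The larger batch and learning rate simply
  rescale the desk schedule; they are not tuned claims about the full
  recipe.

Training minimizes binary cross-entropy (numerically stabilized on logits)
with the Adam optimizer (β₁ = 0.9, β₂ = 0.999, ε = 1e-8). Cross-entropy is
evaluated against the stored labels directly, so soft labels from smoothing
(below) need no special loss. When a two-class validation set is supplied,
the epoch with the best validation auPRC is retained — auPRC rather than
loss or accuracy, because model selection happens under class imbalance.
Everything stochastic (He initialization, shuffling, dropout) draws from
R's RNG, so a single integer seed reproduces a run exactly.

The layer engine stores activations as column-major `(H, W, C, N)` arrays.
The hot kernels — 'same' stride-1 convolution via per-sample im2col plus
BLAS gemm, 2 × 2 max pooling, leaky ReLU, spatial batch normalization — are
implemented in C++ with plain-R reference implementations kept in the
package; the test suite checks the two paths agree to near machine
precision and that backpropagation matches numerical gradients.

## Datasets and class imbalance

Positives are experimentally supported (or synthetic) miRNA:target pairs.
Negatives are *shuffles*: each positive target is re-paired with `k`
miRNAs drawn from the experiment's own miRNA pool, excluding any miRNA that
pairs positively with that target (exact sequence identity; no similarity
filtering). Drawing is per target — without replacement until the
admissible pool is exhausted, then with replacement — so target composition
is identical across classes and prevalence is exactly `1/(1 + k)`.
`assemble_ratio()` builds 1:1, 1:10, 1:20 or 1:100 datasets; splits are by
record by default, with an option to keep duplicate sequence pairs, or
whole groups, inside one partition.

Under heavy imbalance most negatives are uninformative. The package
implements instance-hardness label smoothing: the hardness of a sample is
the estimated probability that a committee of scorers misclassifies it (for
a negative, the mean predicted binding probability). Hard negatives —
false-positive-prone shuffles — are the discriminative ones. Two composable
steps follow:

* `select_hard_negatives()` keeps all positives and the highest-hardness
  negatives until a requested ratio is met (ties broken by hardness, then
  pair identifier, so selection is deterministic);
* `smooth_labels()` replaces each selected negative's hard 0 with
  `map(IH)`, where the map is monotone from [0, 1] onto [0, 0.5]. The
  endpoint 0.5 is deliberate: the hardest samples are made maximally
  uncertain, never flipped into positives.

Design choices where the method leaves room: the committee is five
balanced-trained CNN scorers by default, arranged K-fold style by
`estimate_instance_hardness_oof()` — samples are split into five folds,
member *m* trains on a balanced draw from all folds except *m* and *m + 1*,
and each sample's hardness averages the two members blind to its fold.
In-fold scoring would give optimistically low hardness and systematically
understate how confusable a training sample is. The smoothing map is linear
(`IH/2`) — the stated constraints fix only the range, endpoints and
monotonicity, and a linear map adds no extra shape assumptions; any
compliant map can be passed via `smoothing_policy()`. Smoothing applies to
negatives only by default, since the point is to temper the majority class.

## Baselines

* `seed_match()` — the binary canonical-site heuristic: does the reverse
  complement of the miRNA 2–7 hexamer occur in the target? All (possibly
  overlapping) offsets are reported; an `N` inside the seed makes the call
  undefined (reported as no match, with a warning). The 2–7 hexamer is used
  rather than the broader 2–8 definition of the seed region: the hexamer is
  the rule the binary classifier is defined by. Because it is binary, no
  curve can be drawn; it is characterized by sensitivity and precision.
* `normalize_energies()` — min-max normalization of minimum-free-energy
  scores so that the most favorable energy scores 1. An all-equal input has
  no range; scores are then defined as 0.5 with a warning rather than
  rejected.
* `import_external_scores()` — adapter for precomputed tables from
  hybridization/co-folding tools. Pairs the tool reported no interaction
  for receive the worst score (0); p-value-style outputs are converted to
  `1 − p` before normalization.

## Evaluation under skew

A pair is predicted positive iff `score >= threshold` — ties predict
positive; the convention matters at the seed baseline's 0/1 scores and is
stated everywhere. Curves put one point per distinct score with ties
grouped. The PR area is non-interpolated average precision
(Σ ΔR · P over descending thresholds), the standard choice under imbalance
and stable under ties; the ROC area is the trapezoid rule. Evaluation is
always on hard labels — smoothing is a training device, so soft labels are
hardened at 0.5 (with a warning) before scoring. Two operating points are
reported by default, a permissive "normal" cutoff at 0.1 and a conservative
"strict" cutoff at 0.5.

`precision_from_rates(tpr, fpr, k) = tpr / (tpr + k·fpr)` makes the
imbalance arithmetic explicit: class-conditional rates (hence auROC and the
seed heuristic's sensitivity) do not depend on `k`, while precision and
auPRC collapse as `k` grows. The test suite verifies both halves — bitwise
ratio-invariance of seed sensitivity across 1:1/1:10/1:100 assemblies of
one positive set, and strict auPRC decay with stable auROC for a fixed
trained scorer against nested negative pools.

## The synthetic generator

`gen_dataset()` plants one of three mechanisms in each 50-nt positive,
mixing them at the composition reported for unbiased chimeric data (40%
canonical, 18% 3'-end-only, remainder non-canonical):

* *canonical* — the reverse complement of the miRNA 2–7 hexamer at a
  uniform offset;
* *three_prime* — the reverse complement of miRNA positions 13–20, with
  rejection sampling guaranteeing no accidental seed complement anywhere in
  the target;
* *noncanonical* — the reverse complement of miRNA positions 3–9 carrying
  one forced internal mismatch, also guaranteed seed-free. This is a
  deliberately simple stand-in for the heterogeneous non-canonical classes
  seen in vivo, which the source data do not enumerate.

Negatives come from `make_negatives()` and are likewise rejection-sampled
to be seed-free, so the seed baseline's recall on synthetic positives
equals the canonical fraction *exactly* and its false-positive rate is 0 —
convenient anchors for testing. Mechanism labels are recorded per pair, so
per-mechanism recall (the synthetic analogue of canonical vs non-canonical
detection) is computable for any scorer via `mechanism_recall()`.

What the generator does **not** emulate: thermodynamic stability, wobble
and bulged duplexes, transcriptome-derived background composition,
expression-weighted sampling, or cross-linking biases of CLASH/CLIP
protocols. Tests passing on synthetic data therefore demonstrate that the
machinery learns planted pairing geometry under controlled conditions — not
that any particular performance level transfers to real chimeric data.

## Numerical choices and degenerate inputs

* Batch normalization: ε = 1e-5, running-stat momentum 0.9; inference uses
  running statistics, so prediction is deterministic and batch-size
  invariant (checked to 1e-6).
* Max-pool ties route the gradient to the first maximum in scan order;
  hardness-selection ties break by pair identifier; both make reruns
  bit-identical.
* Degenerate metric denominators (no predicted positives, single-class
  inputs) return an `NA` undefined-flag or an explicit error rather than a
  silent 0; the all-equal energy table warns and scores 0.5.
* A miRNA shorter than 6 nt has no seed and is rejected; shorter-than-20
  miRNAs are `N`-padded (never stretched), and `N` never pairs.
* Mechanism counts in the synthetic mixture are floored fractions with the
  remainder assigned to the non-canonical class, so counts are
  deterministic at any `n_pos`.

## Desk-scale test conditions

The test suite and the acceptance script run everything at sizes chosen for
a single CPU: learnability uses 4,000 canonical positives plus 4,000
shuffled negatives with a 500-positive held-out set; the ratio-stability
check trains on 1,000 mixed pairs and evaluates 300 positives against
nested pools of up to 30,000 negatives; the hardness-pipeline comparison
uses 200 positives with a 1:40 pool, a five-member out-of-fold committee,
selection to 1:20, and a 1:100 held-out set, repeated over three seeds with
a majority criterion. These are the package's desk-scale study conditions,
stated here once; the directional claims they test (learned scorer beats
the seed rule on non-canonical sites; hardness-aware imbalanced training
beats balanced training at 1:100) are stochastic properties, not published
performance figures.

## Limitations

* The scorers see only Watson–Crick geometry; thermodynamics and context
  (site accessibility, AU-flanking effects, conservation) are out of scope.
* The non-canonical synthetic mechanism is a single simple pattern; real
  non-canonical repertoires are broader.
* Full-profile training on real CLASH-scale data (tens of thousands of
  pairs, ten epochs at batch 32) is supported but slow in this CPU-only
  implementation; the desk profile exists precisely because of that.
* The CLI stores model checkpoints as RDS files, which are
  version-portable only across compatible R versions.
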