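---
title: "Wrapper-based deep-feature selection with binary metaheuristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper-based deep-feature selection with binary metaheuristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budl)
```

## The problem

Breast ultrasonography produces images in three diagnostic classes —
benign lesion, malignant lesion, and normal tissue. A practical pipeline for
classifying such images without training a network end to end is: extract a
*deep feature vector* per image from the penultimate layer of a pre-trained
convolutional backbone, then train a classical classifier (an SVM) on those
vectors. Penultimate activations are high-dimensional (512–2048 values per
image for the backbones registered here) and many coordinates are irrelevant
or redundant for a three-class ultrasound problem, which hurts both accuracy
and training time. `budl` implements the *wrapper* approach to pruning them:
candidate feature subsets are scored by actually training and testing the
SVM, and a population-based metaheuristic searches the space of subsets.

## The cost model

A candidate subset is encoded as a binary mask over the feature columns and
scored by

$$ M \;=\; \phi\,(1 - \mathrm{Accuracy}) \;+\; \gamma\,\frac{n_{\text{selected}}}{n_{\text{total}}}, $$

where Accuracy is holdout accuracy of an SVM trained on the masked columns.
The defaults $\phi = 0.99$, $\gamma = 0.01$ weight accuracy heavily while
still breaking ties toward smaller subsets: at equal accuracy, dropping
features always lowers $M$, and with $\phi + \gamma = 1$ the cost lies in
$[0, 1]$. `wrapper_cost()` implements exactly this expression;
`evaluate_mask()` supplies the accuracy term.

Fitness-evaluation choices (the source protocol leaves them open; these are
the package's defaults, all configurable via `svm_settings()` and
`cost_config()`):

* **Classifier** — linear-kernel SVM, one-vs-one multiclass (the libsvm
  default), regularization constant $C = 1$. A linear kernel keeps each of
  the thousands of fits inside the wrapper loop fast and is a standard
  default for moderate-dimensional deep features.
* **Standardization** — masked columns are centred and scaled using
  *training-split* statistics only; a column constant on the training split
  maps to zero rather than dividing by zero.
* **Accuracy** — unweighted (micro) accuracy on the single stratified 20 %
  holdout, matching the protocol of reporting one accuracy per run despite
  class imbalance. The same split drives both the fitness and the reported
  result; an inner validation split is deliberately not the default, to
  follow the published protocol (callers worried about selection-on-test
  leakage can pass a different split for final reporting).
* **Holdout** — `stratified_holdout()` gives each class
  `round(count * fraction)` test samples, rounding halves up, never leaving
  a class without a training sample. At the published class sizes
  437/210/133 and fraction 0.2 this yields 87/42/27 test samples
  (624 train / 156 test).

## The search

All ten optimizers — marine predators (MPA), generalized normal distribution
(GNDO), slime mould (SMA), equilibrium optimizer (EO), manta-ray foraging
(MRFO), atom search (ASO), Harris hawks (HHO), Henry gas solubility (HGSO),
pathfinder (PFA), and poor-and-rich (PRO) — share one skeleton:

1. agents hold continuous positions in $[0,1]^d$ (population 10, 100
   iterations by default);
2. a position becomes a mask by the strict threshold rule
   `mask[i] = position[i] > 0.5`;
3. an all-zero mask is *repaired* by activating one uniformly chosen bit —
   no evaluated mask is ever empty;
4. positions are clipped to the box after every update;
5. the best mask ever evaluated is tracked globally (elitism), so the
   convergence trace is non-increasing by construction;
6. duplicate masks are served from a cache rather than refit — this changes
   timing only, never results.

The update equations are the canonical ones from each algorithm's original
publication, parameterized as: MPA — FADs effect 0.2, phase constant
P = 0.5, Brownian/Lévy step regimes switching at T/3 and 2T/3, per-agent
memory saving; GNDO — per-dimension generalized-normal exploitation around
the (agent, best, mean) centroid alternating with fitness-directed pairwise
exploration, greedy acceptance; SMA — fitness-ranked oscillation weights,
vibration parameter `arctanh(1 − t/T)`, restart probability 0.03; EO — an
equilibrium pool of the four best-ever agents plus their mean, decay
constant a1 = 2, generation constant a2 = 1, generation probability 0.5;
MRFO — chain/cyclone foraging plus a somersault move with factor 2; ASO —
Lennard-Jones-style interaction among a shrinking K-best neighbourhood with
depth weight 50 and multiplier weight 0.2, velocity integration; HHO —
escape-energy schedule `2·E0·(1 − t/T)` switching exploration, soft/hard
besiege and Lévy-flight dives; HGSO — two gas clusters with
Henry-coefficient temperature updates and worst-agent re-initialization
(the re-initialization scale constant defaults to 1, leaving the canonical
10–20 % fraction); PFA — a perturbed pathfinder step plus follower updates
with a decaying vibration term, greedy acceptance; PRO — the fitter half
repelled from the best poor agent, the poorer half drawn toward a composite
rich pattern, one-coordinate mutation with probability 0.1.

Design choices made where the protocol was genuinely open:

* **Binarization** — the source protocol states the $[0,1]$ box but not the
  continuous→binary rule; a fixed 0.5 threshold is the simplest rule
  consistent with those bounds. The `threshold` argument of
  `optimizer_config()` exposes it.
* **Tie-breaking** — between equal-cost masks the first one found wins,
  which is stable under the seed.
* **Ambiguous constants** — the published parameter table lists
  "Constant = 0.5" for MPA and "Constant = 1" for HGSO without naming the
  symbols; they are mapped to MPA's phase constant P and to HGSO's
  worst-agent re-initialization scale respectively, with other internals at
  their original-publication defaults.
* **Determinism** — a run is fully determined by
  (algorithm, seed, fitness); all randomness flows through R's RNG seeded
  once per run, and the caller's RNG state is restored afterwards.

## Network selection

Per-backbone results feed `select_networks()`: backbones whose optimized
accuracy is *strictly* above 94 % are kept (the rule is "above 94 %", so a
backbone at exactly 94.0 is excluded), their selected columns concatenated
with provenance-tagged identifiers (`concatenate_selected()`), and a final
SVM trained on the concatenation (`final_classifier()`). Which algorithm's
accuracies feed the threshold is configurable; the default expectation is
the per-backbone best performer, which the reference table shipped in
`inst/extdata/eo_reported_accuracy.csv` reflects (the equilibrium optimizer
led every backbone there, with ResNet-50 at 94.7 % and Inception-ResNet-v2
at 94.2 % the only two above the bar). Whether a second optimization pass
runs on the concatenated vector is not fixed by the source protocol; both
modes exist, and the default is a plain SVM on the concatenated selected
features, matching the "select and concatenate" wording.

## The backbone registry and extraction backends

`list_backbones()` pins the 16 supported backbones and their
penultimate-layer ("before the softmax") feature lengths — e.g. ResNet-18
→ 512, ResNet-50 → 2048, DenseNet-201 → 1920, Inception-ResNet-v2 → 1536.
Some pinned lengths (ShuffleNet = 544, NASNet-Mobile = 1056,
DarkNet-19 = 1000) follow the model zoo the reference results were produced
with and differ from other frameworks' variants of the same names; the
registry is therefore *authoritative*: `extract_features()` rejects any
backend whose output length disagrees with the pinned value, rather than
trusting the backend. Preprocessing is backbone-native — resize to the
registered input size, replicate single-channel images to three channels,
then the backbone's standard normalization.

Two backend flavours exist. The `"mock"` backend is deterministic
pseudo-extraction (a byte-hash-seeded uniform draw offset by the image's
mean intensity) satisfying the full extraction contract; it exists so the
entire pipeline is testable without network weights. A real backend must be
supplied by the user as `extract_one = function(path, spec)` backed by a
deep-learning runtime; `extraction_backend("real")` without one raises an
actionable error. Reproducing the published per-backbone accuracies
additionally requires the public 780-image breast-ultrasound collection and
pretrained weights, and is therefore an external exercise, not part of the
test surface.

## What the synthetic generator emulates — and what it does not

`make_synthetic_features()` plants `k_informative` Gaussian columns whose
class means are staggered by `separation` standard deviations (class $c$
mean $= (c-1)\cdot\text{separation}$, unit SD) among class-independent
noise columns. Defaults — three classes of 50 samples, 200 features, 10
informative, separation 2 SD — make the three classes strongly but not
perfectly separable with the full feature set, so selection has measurable
headroom, which is the regime the method targets. `make_synthetic_images()`
draws speckled grayscale PNGs with a smooth bright ellipse (benign), a
smaller irregular star (malignant), or speckle only (normal), in the
folder-per-class layout the loader expects.

These fixtures give known ground truth (`truth_mask`) and analytic
separability, which real ultrasound features do not: real deep features are
correlated, non-Gaussian, and carry no oracle labels for "informative". A
passing planted-recovery test therefore shows the search machinery works —
it does not certify clinical performance on real images.

## Problem sizes and observed behaviour

The test suite works at desk scale, chosen so the full suite runs in a few
minutes: invariant checks (elitism, bounds, determinism) use the sphere
benchmark on $[0,1]^8$ across all ten algorithms and three seeds;
planted-feature recovery uses the generator defaults (150 samples, 200
features); exhaustive-oracle comparisons use 12-feature tables where all
4095 masks can be enumerated. On those oracle instances the 0.99/0.01
weighting makes relative cost bands extremely tight — near-perfect-accuracy
optima have costs of order $10^{-3}$, below one holdout-accuracy quantum —
so closing the last few percent of relative cost amounts to recovering the
exact global optimum. The stronger schemes (MPA, HGSO, EO, and often PFA,
MRFO, HHO) do reach the enumerated optimum on most seeds; GNDO, SMA, ASO
and PRO typically stop one feature or one test-misclassification short,
consistent with the sizeable accuracy spread among the same ten algorithms
in the reference results. The benchmark campaign mirrors the published
protocol (ten repeated 80/20 splits shared across cells, sample-SD
summaries; the SD convention is not stated in the source and sample SD is
this package's documented choice).

## Known limitations

* Real-backbone extraction depends on an external deep-learning runtime and
  weights; only the contract (dimension pinning, ordering, determinism of
  the mock) is testable here.
* Fitness uses the same holdout for selection and reporting, as the source
  protocol implies; this overestimates generalization slightly.
* Timing columns are wall-clock and hardware-dependent; they are reported
  but never asserted.
* The binary encoding uses a fixed threshold; S/V transfer functions are a
  known alternative that may explore more masks at equal budget.
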