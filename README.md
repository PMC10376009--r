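# budl

Wrapper-based deep-feature selection for breast-ultrasound classification.

Classifying breast ultrasound images into benign, malignant and normal is a
standard transfer-learning task: each image is summarized by the
penultimate-layer activation of a pre-trained convolutional backbone
(512–2048 values per image), and a classical SVM is trained on those deep
features. Most of those coordinates are irrelevant for the three-class
problem. `budl` prunes them with *wrapper* search: a binary mask over the
feature columns is scored by actually training a linear SVM on the masked
training features and testing on a stratified 20 % holdout, blended with a
sparsity penalty

    M = φ · (1 − Accuracy) + γ · n_selected / n_total,    φ = 0.99, γ = 0.01

and ten population-based binary metaheuristics search for the mask
minimizing M: the marine predators algorithm (MPA), generalized normal
distribution optimization (GNDO), the slime mould algorithm (SMA), the
equilibrium optimizer (EO), manta-ray foraging optimization (MRFO), atom
search optimization (ASO), Harris hawks optimization (HHO), Henry gas
solubility optimization (HGSO), the pathfinder algorithm (PFA), and
poor-and-rich optimization (PRO). Agents move in `[0,1]^d` (population 10,
100 iterations by default), are binarized at 0.5, repaired if empty, and
the best mask ever evaluated is retained (elitism). A final *network
selection* stage keeps the backbones whose optimized accuracy is strictly
above 94 %, concatenates their selected features, and trains the final SVM.

The package is aimed at researchers benchmarking feature-selection
metaheuristics and at practitioners reducing deep-feature tables before a
classical classifier. Everything runs on plain CSV feature tables; a
deterministic mock extraction backend and a synthetic generator with
planted informative features make the whole pipeline testable without
images, weights, or downloads.

## Worked example

```r
library(budl)

# 150 samples, 200 features, 10 informative (class means 2 SD apart)
syn   <- make_synthetic_features(synthetic_spec(seed = 42))
split <- stratified_holdout(syn$table$labels, 0.2, seed = 42)

full <- evaluate_mask(syn$table, split, rep(1, 200))
sprintf("full features: accuracy %.3f, cost %.4f", full$accuracy, full$cost)
#> "full features: accuracy 0.967, cost 0.0430"

res <- run_optimizer(syn$table, split, cost_config(),
                     optimizer_config("eo", seed = 42))
res
#> <selection_result> eo (seed 42): cost 0.000250, accuracy 1.0000, 5/200 features, 3.3s
sum(res$best_mask * syn$truth_mask)
#> 3
```

The equilibrium optimizer raises holdout accuracy from 0.967 (all 200
features, cost 0.0430) to 1.000 while keeping only 5 of 200 columns (cost
0.00025 = 0.01·5/200), three of them planted informative columns — with 30
test samples, two informative columns already separate the classes, so the
sparsity term prunes the rest. `run_benchmark()` scales this to the full
repeats × backbones × algorithms grid and writes mean ± SD accuracy,
feature-count and timing summaries; `select_networks()` /
`concatenate_selected()` / `final_classifier()` implement the >94 %
network-selection stage.

Deep features from real images come via `extract_features()` with a
user-supplied backend mapped over a folder-per-class image directory; the
backbone registry (`list_backbones()`) pins the expected penultimate-layer
dimension for 16 backbones and rejects any backend that disagrees.
Reproducing the published per-backbone accuracies requires the public
780-image breast-ultrasound collection plus pretrained weights (ResNet-50
deep features with EO average 94.7 ± 2.5 % there) and is an external
exercise — see the vignette.

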