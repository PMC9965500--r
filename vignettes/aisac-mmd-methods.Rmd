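---
title: "AISAC-MMD: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AISAC-MMD: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisacmmd)
```

## The problem and the model

Clinical tabulated data — biopsy findings, mammographic assessments,
survival registries — typically mix numeric measurements with categorical
findings, omit values for many cells, and are class-imbalanced because
positive findings are rarer than negative ones. AISAC-MMD is a
prototype-generation classifier for exactly this setting. It maintains a
small set of synthetic representative instances ("antibodies" in the
immune metaphor) per class and classifies an unknown instance by the
class of its nearest prototype. Crucially, nearness is measured by a
heterogeneous dissimilarity that is *defined* on incomplete mixed
instances, so neither training nor test data are ever imputed or
re-encoded.

### Dissimilarity

The package uses the Heterogeneous Euclidean-Overlap Metric (HEOM): per
attribute, distance 1 if either value is missing; 0/1 equality for
nominal attributes; range-normalized absolute difference, clipped to
[0, 1], for numeric attributes; aggregated as the root of the sum of
squares. Consequences worth noting:

* The per-attribute distance is always in [0, 1] and the instance
  distance in [0, sqrt(m)], so no attribute can dominate by scale alone.
* Missingness is informative only in the weak sense "maximally
  dissimilar"; two instances missing the same attribute are still at
  distance 1 on it.
* Normalization ranges come from the *construction* partition only,
  never from validation or test data; test values outside the training
  range are clipped so the bound sqrt(m) survives.
* A numeric attribute with zero (or undefined) training range is
  compared by equality; this avoids division by zero while keeping
  discrimination.

The dissimilarity is a named, pluggable strategy
(`get_dissimilarity("heom")`, `register_dissimilarity()`); alternative
metrics can be slotted in without touching the training code. The
unnormalized root-sum-of-squares form is used (no division by the
attribute count); since the nearest-prototype decision only compares
distances with a fixed attribute count, the choice does not affect
predictions.

### Training

`aisac_fit()` first splits the training set by a stratified hold-out into
construction and validation partitions. Per class, round-half-up of
`fraction * n_c` instances go to construction, clamped so both sides keep
at least one instance when the class has two or more; a singleton class
goes entirely to construction so that every class is represented in the
memory. Then four phases run:

1. **Bags.** Per class `c`, `max(1, ceil(n_c / bag_size))` seeds are
   drawn without replacement by the seeded generator; the remaining
   instances of the class join their nearest seed (ties to the lowest
   seed index). Bags are class-pure by construction, and the cost is
   O(n x bags), in line with the method's low-complexity design.
2. **Merge.** Each bag becomes one prototype: attribute-wise mean of the
   observed member values for numerics, mode for nominals with ties
   resolved toward the category earliest in schema order. An attribute
   observed in *no* member stays missing in the prototype; the HEOM
   missing rule then handles it at classification time. We deliberately
   do not fall back to class- or dataset-level statistics here: doing so
   would make a singleton bag's prototype differ from its instance, and
   the package treats the exact reduction of the degenerate
   configuration (bag size 1, zero generations) to 1-NN/HEOM over the
   construction set as a defining contract — it is what makes the
   classifier independently verifiable against a plain nearest-neighbour
   oracle. The substitution of means/modes for missing values thus
   happens precisely where observed values exist to support it, and the
   original instances are never modified.
3. **Movement.** Construction instances are visited in seeded random
   order; for each, every same-class destination bag is evaluated by
   re-merging only the two affected prototypes, and the single best move
   is accepted only if the validation balanced accuracy of the
   1-nearest-prototype classifier *strictly* increases. Optimizing on
   the validation partition (rather than on construction data) is the
   package's reading of the method's anti-overfitting intent; it also
   makes the fitness the same quantity throughout.
4. **Clonal selection.** Every prototype spawns `n_clones` perturbed
   copies — numeric attributes get Gaussian noise with standard
   deviation `mutation_rate * range_a`, clipped to the training min/max;
   nominal attributes are resampled uniformly with probability
   `mutation_rate`; missing attributes stay missing — and is replaced by
   its best clone only on strict improvement.

Phases 3 and 4 alternate for up to `max_generations` generations with
early stopping after `patience` generations without improvement. Because
every acceptance is strict, the sequence of accepted fitness values is
non-decreasing (elitism); the final state is automatically the best
seen, and the frozen `fitness` re-evaluates exactly on the stored
validation partition.

### Classification

`classify()` returns the class of the HEOM-nearest prototype. Exact
distance ties are broken toward the class with the larger training
count, then the lower class index; an all-missing instance is equidistant
(sqrt(m)) from every prototype and therefore receives the majority
class — the only defensible answer in the absence of any evidence.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `holdout_fraction` | 0.7 | construction share of the training set; the most common hold-out convention |
| `bag_size` | 5 | target instances per bag; ~n/5 prototypes per class balances compression against resolution |
| `max_generations` | 10 | outer iterations; matches the generation counts customary for clonal-selection classifiers |
| `n_clones` | 5 | clones per prototype per generation |
| `mutation_rate` | 0.1 | clone perturbation scale (fraction of the training range; resampling probability for nominals); the customary clonal factor magnitude |
| `patience` | 3 | early-stop stall length, in generations |
| `seed` | 1 | drives every stochastic stage through deterministic sub-seeding |

No automatic parameter tuning is performed or provided; the defaults are
used as-is throughout the package's own experiments.

## Evaluation protocol

Balanced accuracy is the mean per-class recall from the confusion
matrix. Classes without true instances are excluded from the average
(`k_effective`), avoiding 0/0 recalls; with equal class supports the
measure coincides with plain accuracy. The imbalance ratio
(majority/minority count) is reported at full precision and *truncated*
to two decimals for display (187/175 renders "1.06"), matching the
convention of published benchmark tables.

The Wilcoxon signed-rank comparison follows the conventions needed for
small benchmark collections: absolute differences are ranked with
average ranks for ties, zeros included; the ranks of zero differences
are split evenly between R+ and R- (one zero dropped, n reduced by one,
if their count is odd), so R+ + R- = n(n+1)/2 always; the two-sided
p-value uses the normal approximation with continuity correction applied
to the smaller rank sum. A known limitation, verified by the suite's
enumeration oracle: at very small n this approximation is
anticonservative near the decision boundary (e.g. n = 5 with a
unanimous sign pattern gives exact p = 0.0625 but approximate
p = 0.031), so accept/reject decisions for n below about 10 should be
read with care. At n = 10 — the size of the benchmark collection the
package ships — decision agreement with exact enumeration holds across
the whole range of rank sums.

`best_count()` counts rows where the focal classifier ties or beats
every competitor; ties count as wins, the convention used when benchmark
tables bold tied winners.

## The synthetic generator

`generate_mixed()` draws labels from fixed class proportions (every
class is guaranteed at least one instance), numeric attributes from
class-conditional Gaussians with unit within-class standard deviation
and class means offset by `class_separation`, and nominal attributes
from class-conditional categorical distributions that put mass
`1/q + (1 - 1/q)(1 - exp(-separation/2))` on a class-preferred category
(rotating per attribute). The formula is exactly uniform at separation
0 for any number of categories, so "no separation" genuinely means "no
signal" for every attribute kind; for two categories it reduces to the
natural 0.5-plus-bonus form. Missingness is injected MCAR — each
predictor cell independently with the same probability — because that is
the minimal mechanism exercising the HEOM missing rule and the merge
substitution without confounding the class signal.

Defaults (300 instances, 70/30 classes, 4 numeric + 3 nominal
attributes, separation 2, 5% missing) emulate a mid-sized clinical
benchmark: a few hundred instances, mixed attribute kinds, an imbalance
ratio above the conventional 1.5 threshold, and visible missingness.

What the generator does *not* emulate: attribute correlation (no copula
structure), informative missingness (no MAR/MNAR), label noise, and
heavy-tailed or multimodal within-class distributions. Passing tests on
generated data therefore demonstrate correctness of the mechanics and
sane behaviour under class overlap, imbalance and MCAR missingness — not
performance claims on real clinical data.

## Numerical and reproducibility choices

* One user seed drives everything; stage seeds are derived as
  `(seed * 7919 + offset * 104729) mod 2147483587`, so stages are
  decoupled and a single integer reproduces a whole experiment,
  including from the command line.
* All tie-breaks are deterministic: mode ties toward the earliest schema
  category, nearest-seed ties toward the lowest seed index,
  nearest-prototype ties by class count then class index, 1-NN baseline
  ties by dataset order.
* Model files and numeric CSV/ARFF cells are written with 17 significant
  digits, so write/read round trips are exact and re-serialization is
  byte-identical.
* Degenerate inputs have defined behaviour: singleton classes go to
  construction; an empty validation partition freezes the initial
  prototypes (fitness undefined); `max_generations = 0` skips
  refinement entirely, yielding the 1-NN-equivalent memory when
  `bag_size = 1`.

The suite's statistical checks run at deliberately modest problem sizes
chosen to keep the full suite fast while leaving comfortable margins:
synthetic-recovery checks use 300 training instances over 10 seeds, the
degenerate-equivalence check 200 random datasets of 25–60 instances, the
HEOM brute-force comparison 1000 random pairs, and the Wilcoxon
enumeration oracle 500 samples with n ≤ 12.

## Known limitations

* The movement pass evaluates every candidate move against the full
  validation partition; training is O(generations x n x bags x
  validation). Fine for the hundreds-to-thousands-of-instances regime
  the method targets, but not for large datasets.
* Balanced accuracy on a small validation partition is a coarse fitness
  signal; with very few validation instances many candidate moves tie
  and refinement stalls early.
* HEOM's "missing = maximally distant" rule is a modeling choice, not an
  inference about the missing value; under heavy informative
  missingness it can systematically distort neighbourhoods.
* The Wilcoxon normal approximation is anticonservative below n ≈ 10,
  as discussed above.
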