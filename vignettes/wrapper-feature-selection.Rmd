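---
title: "Wrapper-based metaheuristic feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper-based metaheuristic feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbmfs)
```

## The problem

Deep features — activations taken from the layer before softmax of a
pretrained convolutional network — turn an image collection into a
samples-by-features table with hundreds to thousands of columns. Training
a classifier such as an SVM directly on such a table wastes capacity on
redundant and irrelevant columns. Wrapper feature selection searches the
space of column subsets, scoring each candidate by actually training and
validating the classifier on it. Because the subset space is exponential,
the search is delegated to population-based metaheuristics operating on a
continuous relaxation of the subset indicator.

`wbmfs` implements this machinery end to end for banks of deep-feature
tables (one table per backbone network): eight binary metaheuristics, the
SVM wrapper cost, a network-selection-and-concatenation pipeline,
per-class confusion-matrix metrics, and an extreme-point cropping
preprocessor for the grayscale brain-MRI images such features are
typically extracted from.

## The wrapper cost

Every candidate subset is scored by

$$ I \;=\; \omega\,(1-\mathrm{accuracy}) \;+\;
   \sigma\,\frac{n_\text{selected}}{n_\text{total}}, $$

minimized over subsets, with $\omega = 0.99$ and $\sigma = 0.01$ by
default. Accuracy is the validation accuracy of the classifier trained on
the masked table under a fixed split; the second term charges a small
rent per retained feature. With these weights an accuracy edge larger
than $0.0102$ always outweighs any possible size difference, so the size
term only arbitrates near-ties.

The classifier defaults are a linear-kernel SVM with $C = 1$ and
per-feature standardization fitted on the training fold only
(`classifier_config()`). Deep features are high-dimensional and roughly
linearly separable after good backbones; a linear SVM is the conventional
wrapper choice and is fast enough to be called hundreds of times per
search. The split defaults to a stratified 0.2 holdout
(`split_spec()`); five-fold cross-validation is available through the
same interface. One split is materialized per search and reused for every
subset (`cached_evaluator()` memoizes by mask), so all costs in a run are
measured on identical validation data and repeated masks cost nothing.
Whether to measure the *final* model on the same split or a fresh one is
exposed via the pipeline's split seed; the default reuses the search
split, matching the apparent practice of the search grids this package
emulates, at the price of an optimistic bias discussed below.

Empty masks score the worst possible cost $\omega + \sigma$ instead of
raising, so optimizer loops are total; `apply_mask()` at the API boundary
still rejects them.

## The eight optimizers

All algorithms share the same skeleton (`run_optimizer()`): agents live
in $[0,1]^D$, every candidate position is thresholded at $0.5$
(`binarize_position()`; the S-shaped transfer reduces to a strict
`> 0.5` under the deterministic convention we default to), and an elitist
tracker records the best mask ever evaluated, independent of any
algorithm-internal memory, breaking ties toward fewer features and then
toward the earlier evaluation. Positions are clamped (not reflected) at
the bounds. One seeded generator drives every stochastic draw of a run,
so runs are bit-reproducible. Budgets default to 50 iterations with 10
agents. Per iteration each algorithm evaluates one candidate per agent,
with two documented exceptions: the marine-predators step evaluates a
second time after its fish-aggregating-devices perturbation, and the
Harris-hawks rapid-dive branches probe up to two extra candidates per
hawk.

The update rules follow the algorithms' original publications (marine
predators, atom search, Harris hawks, butterfly, whale, grey wolf, bat,
firefly), parameterized exactly by the published operating table (e.g.
FADs effect 0.2, depth weight 50, Lévy exponent 1.5, modality 0.01 with
switch probability 0.8, spiral constant 1, bat frequencies in $[0,2]$
with constant 0.9 and maximum loudness 2, firefly absorption 1 with
control 0.97). Where those publications leave scale constants open — and
several were calibrated for wide benchmark domains rather than the unit
cube — this package fixes them as follows, validated against enumerated
small landscapes (below):

* **Atom search**: the Lennard-Jones-style interaction repels below and
  attracts above the equilibrium distance; its envelope decays as
  $e^{-5t/T}$ so atoms keep interacting over a 50-iteration run (the
  original $e^{-20t/T}$ freezes the population after the first fifth);
  velocities are bounded to half the cube. Masses are exponentially
  ranked and normalized to sum to one (`aso_masses()`).
* **Butterfly**: the sensory modality $c$ starts at 0.01 and grows each
  iteration by $0.5/(cT)$; the stimulus is the agent's cost magnitude
  raised to the power exponent $a = 0.1$ (the original paper's value,
  configurable). The random factor $r^2$ in both moves is drawn per
  dimension; a scalar draw makes all coordinates cross the threshold in
  lockstep, which removes most of the mask diversity the search relies
  on.
* **Bat**: pulse rates grow geometrically, $r_t = r_{\max}(1-0.9^t)$,
  reading the published "constant = 0.9" the same way for loudness decay
  and pulse-rate growth; the saturating $1-e^{-0.9t}$ form ends all
  local walks within three iterations. Loudness decay remains
  acceptance-gated (a bat's loudness is $2\cdot0.9^k$ after $k$ accepted
  updates); the local walk around the best is offset by
  $U(-\tfrac12,\tfrac12)$ times the mean loudness per dimension, and
  velocities are bounded to the cube's width.
* **Grey wolf**: the three leaders are the three best solutions seen so
  far; populations smaller than three pad the leader set by repeating
  the best.
* **Marine predators**: phase boundaries at thirds of the run; the
  narrative "reproduction" phase of some descriptions has no canonical
  counterpart and is not a distinct phase.

These are implementation choices of this package, made once and
documented here; the published parameters themselves are never altered.

### Validation against an enumerated oracle

Because subset spaces up to $D = 20$ can be enumerated,
`exhaustive_oracle()` provides ground truth: it scores every non-empty
mask and returns the minimum under the same tie-breaking as the
optimizers. The test suite plants a landscape at $D = 8$ (one feature
worth perfect accuracy, the rest chance), confirms the enumerated
optimum analytically ($I = 0.00125$), and requires each of the eight
algorithms to attain it in at least 18 of 20 seeded runs at the default
budgets. Across 100 development seeds six algorithms attained it in
every run and the weakest in 92–99.

## What the wrapper can and cannot recover

The synthetic generator (`generate_feature_bank()`) emulates a
multi-network deep-feature bank: per-class Gaussian mean shifts on a
small planted set of informative columns, optional redundant columns
(informative plus fresh noise), and pure-noise columns. Class mean
patterns are chosen so that, when there are at least as many informative
columns as class boundaries, *every* informative column is necessary to
separate some pair of classes (baseline class plus one shifted class per
column); with fewer informative columns than classes, binary-code
patterns keep all classes distinct. Effect size is parameterized in
noise-SD units so power is analytically anticipatable. The default
desk-scale bank — four classes of 60 samples, two networks of 64 and 48
columns with three informative each — runs the full pipeline in about a
minute; it deliberately does *not* model the heavy tails, sparsity and
inter-column correlation of real CNN activations, so passing tests
demonstrate the machinery, not performance on real scans.

A structural caveat the package surfaces honestly: with a validation set
of modest size, the *selection* step overfits the validation data. On an
effect-size-3 bank with 12 columns and 240 samples, enumerating all 4095
masks shows the cost-optimal subset contains the three planted columns
*plus* two to four pure-noise columns — the best-of-thousands luck on a
48-sample holdout (or even on five-fold CV) is worth a few accuracy
points, which dwarfs the size rent $\sigma/D \approx 0.0008$. No search
algorithm can beat that, since the overfit subsets genuinely score
better. Consequently the searches recover *every* planted feature in
virtually all runs (coverage 1), while exact-set agreement (Jaccard
$\ge 0.8$) is rare for all eight algorithms alike. The acceptance suite
asserts exact-set recovery and is expected to fail there; the acceptance
script reports both rates so the distinction stays visible. At null
effect the generator produces no recoverable signal and the suite checks
that per-column tests reject only at nominal rates, guarding against
train/validation leakage.

## Selection pipeline

`run_wbm_pipeline()` searches every network's table with every requested
algorithm (seeds derived from a master seed by a counter scheme, so
adding a network leaves the others' random streams untouched), names a
per-network winner by maximum accuracy (cost, then subset size as
tie-breaks — the selection rule is phrased in accuracy), keeps the
networks whose winner *strictly* exceeds the threshold (default 0.94),
concatenates the masked survivors by sample-identifier-checked
column-binding, and evaluates the final SVM under both the holdout and a
five-fold scheme, reporting per-class TPR/FNR/PPV/FDR and overall
accuracy. Per-class rates are exact complements before rounding
(TPR + FNR = PPV + FDR = 100) and are displayed with half-up rounding to
one decimal (so 3 misses of 80 prints as 3.8). Metrics with an empty row
or column are reported as explicitly undefined, never as zero. The final
concatenated model's accuracy is reported *alongside* the survivors'
individual search accuracies rather than asserted to exceed them — the
gain from concatenation is an empirical matter, not a guarantee.

## Preprocessing

The cropping chain for grayscale scans is threshold → morphological
opening → extreme points → crop → bilinear resize
(`preprocess_scan()`). Numerical conventions: the threshold defaults to
Otsu's histogram criterion with manual override; the structuring element
defaults to a 3×3 square applied as two erosions then two dilations;
coordinates are 0-based row-major with an inclusive bounding box; the
crop margin defaults to 0; resizing uses corner-aligned bilinear
interpolation, so resizing a crop to its own size is exact. On the
bounded image window, pixels beyond the border count as foreground for
erosion and background for dilation — the convention under which erosion
and dilation are exact duals, verified against brute-force definitions
on random masks. The synthetic scan generator (a bright ellipse with
optional noise and isolated speckles, with its ground-truth bounding
box) closes the loop: in the noiseless case the recovered box is exact,
and opening removes sub-element speckles without disturbing it.

## Known limitations

* The feature-table contract starts at extracted deep features; running
  pretrained CNNs is out of scope (an adapter may map image batches to
  tables, but backbone names are accepted as tags only).
* Wrapper accuracies measured on the reused search split are
  optimistically biased; use a fresh final seed for honest estimates.
* The bat and butterfly searches remain the weakest of the eight on
  planted landscapes — consistent with their relative standing in
  published search grids of this family — even after the unit-cube
  adaptations above.
* Single-frame PNG/TIFF only; no DICOM/NIfTI, no intensity normalization
  across scanners.

## Problem sizes used in the shipped experiments

The test and acceptance experiments use $D = 8$ (enumeration 255 masks,
20 seeds per algorithm) for oracle equivalence, $D = 12$ with the
default 240-sample bank and 10 seeds per algorithm for the recovery
study, and 16×16 random masks for the morphology oracles — sizes chosen
so the full suite exercises every code path in a few minutes while the
enumerated ground truth stays exact.
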