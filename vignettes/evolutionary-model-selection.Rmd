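---
title: "Evolutionary joint selection of features and hyperparameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary joint selection of features and hyperparameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

evotune searches jointly over *which features* a supervised model uses and
*which hyperparameter values* it is trained with, using a population-based
evolutionary loop whose fitness is the Bayesian information criterion (BIC)
computed from out-of-fold predictions. This vignette describes the method, its
parameters, and the numerical choices made in the implementation.

## The model being optimized

A candidate solution (a *chromosome*) is a pair: a named vector of
hyperparameter values, and a subset of feature names drawn from a fixed pool.
Three inner model families are supported, each with a three-parameter
(or two-parameter) search profile:

* **linear** — elastic-net regression/classification via glmnet. The two genes
  are an L1 and an L2 penalty weight, mapped bijectively to glmnet's
  `(lambda, alpha)` as `lambda = l1 + l2`, `alpha = l1 / (l1 + l2)`.
  For regression the response is standardized internally before fitting and
  predictions and coefficients are mapped back, so the penalty acts on a fixed
  scale regardless of the response's variance.
* **tree** — gradient-boosted trees via xgboost; genes are `max_depth`
  (integer), `gamma`, and `alpha` (L1 regularization). Trees run
  single-threaded so results are reproducible.
* **net** — a small feed-forward network trained with Adam; genes are the
  learning rate and Adam's `beta1`/`beta2`. The network is implemented in
  plain R (full-batch updates, ReLU hidden layers, early stopping with
  patience 3 on a 10% validation split) so that training is exactly
  deterministic under R's RNG.

Each gene has a box range and a fixed mutation shift; integer genes round half
away from zero after recombination.

## Fitness

A chromosome is scored by k-fold cross-validation restricted to its feature
subset, with `k = ceiling(n_samples / n_features)` (clamped to at least 2 and
optionally capped). Out-of-fold predictions feed the BIC:

* regression: `n * ln(max(SSE/n, 1e-12)) + p * ln(n)`
* classification: `-2 * sum(ln p_hat) + p * ln(n)`, probabilities clipped to
  `[1e-12, 1 - 1e-12]`

where `p` is the number of selected features plus one. Lower is better; the
feature-count term makes parsimony part of the objective. Classification folds
are stratified; if a fold loses a class, k is reduced and the evaluation
retried. A failed fit receives infinite BIC rather than aborting the run.

## The evolutionary loop

Each generation of the standard phase holds `n` models (default 100, must be a
multiple of 10). Models are ranked by BIC (ties: fewer features first) and the
next generation is composed exactly as:

* the top 40% are paired (1st with 2nd, 3rd with 4th, ...) and each pair
  produces one **recombined** child: hyperparameters are the arithmetic mean
  of the parents, the feature subset is copied from the higher-ranked parent
  (0.2 n children);
* the top 20% are **mutated**: every hyperparameter moves by exactly its shift
  in a random direction, clamped to its range; features are unchanged (0.2 n);
* the remaining 60% of slots are filled with fresh **random** chromosomes.

The run keeps a rolling archive of the 100 best distinct models seen and a
convergence queue holding the three best BIC values per generation. It stops
at a plateau: after more than `window` generations (default 20), when the best
value seen up to `window` generations ago has improved by less than
`tol * |best|` (relative tolerance, default `1e-4`).

## Warm-started recursive feature pruning

Because children inherit their elite parent's feature subset verbatim,
standard-phase lineages refine hyperparameters but never drop features. The
second phase prunes:

1. Per-feature importances (absolute coefficients for linear models, split
   gains for trees, permutation importances for networks) are averaged over
   the archived models containing each feature.
2. The archive's (feature count, validation performance) pairs form a curve;
   the **elbow** is the point of the upper envelope with maximum perpendicular
   distance to the chord joining its endpoints (smallest count if the envelope
   is affine).
3. A threshold schedule is built: base = importance of the elbow-th ranked
   feature, plus 0–4 population standard deviations of the nonzero
   importances.
4. For each threshold, the feature pool is restricted to features at or above
   it (empty pools are skipped) and an independent half-size evolution run
   (population `0.5 n`, composition 0.2 n recombined / 0.1 n mutated /
   0.2 n random) starts from a fresh random generation. The stage whose best
   model has the lowest BIC wins.

`run_iel()` chains both phases and returns the overall best model. If the
archive contains fewer than three distinct feature counts the elbow is
undefined and the warm phase is skipped.

## Data preparation

`prepare_partition()` applies, in order: drop features with more than 40%
missing values; clip values outside mean ± 3 SD (bounds are recorded so the
transform can be replayed); impute missing cells by masked non-negative matrix
factorization (multiplicative updates on observed cells only; matrices with
negative entries are shifted up and back); min–max scale to [0, 1]; and pick,
per feature, whichever of identity, rank-based normal quantile transform, or
Yeo–Johnson power transform best normalizes it (score = |skewness| + |excess
kurtosis|). For classification, a continuous target can be discretized at a
cutoff (strictly above = positive) and classes are balanced by SMOTE-style
interpolation followed by edited-nearest-neighbour cleaning. Preparation
statistics are always fitted within a partition, never across the
train/validation split (70/30 by default).

## Synthetic data and oracles

`generate_synthetic()` plants a known linear signal (optionally with
interactions, redundant copies, skewed noise features, and MCAR missingness)
so that recovery can be checked against ground truth. Two independent oracles
exist for verification: `oracle_best_subset()` enumerates every feature subset
(up to 15 features) with unpenalized least-squares/logistic fits under the
same fold scheme and BIC formulas, and the unit tests recompute BIC, elbow
geometry, and ridge solutions from first principles.

## Design decisions and limitations

* Problem sizes in the tests and the acceptance script (populations of 10–20,
  synthetic instances of 120–300 samples) are desk-scale choices of this
  package so that the whole suite runs in minutes on one CPU; the method
  itself defaults to population 100.
* All randomness flows through R's ambient RNG; top-level runners take a
  `seed` argument and are bit-for-bit reproducible.
* Known limitation: with small populations the elite lineage can fixate on a
  single feature subset, filling the archive with hyperparameter variants of
  one subset. The archive then has a single feature count, the elbow is
  undefined, and the warm phase cannot prune — the best model may retain
  surplus features relative to an exhaustive best-subset oracle. Larger
  populations (more random immigrants per generation) reduce this effect.
* The feed-forward network is intentionally minimal (full-batch Adam, no
  dropout or batch normalization); it exists so the three-family interface is
  complete and deterministic, not as a competitive deep-learning stack.
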