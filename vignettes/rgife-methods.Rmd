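---
title: "Ranked-guided iterative feature elimination: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked-guided iterative feature elimination: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgife)
```

## The problem and the procedure

Given an `m × p` matrix of samples by features (gene expression values,
typically `p ≫ m`) and one discrete class label per sample, the package
searches for a small feature subset whose cross-validated classification
accuracy matches that of the full matrix. The search is a guided backward
elimination:

* **Ranking.** The current feature set is scored by repeated *k*-fold
  DB-SCV: every fold model is a gini-impurity random forest, and the
  impurity-decrease importances of all `k × N` fold models are averaged
  (each model's vector normalised to sum to one first) into a consensus
  ranking. No extra full-data fit is made — the ranking is a by-product of
  the performance estimate, so the features are judged by the same models
  that produced the reference accuracy.
* **Block removal.** `blockSize = floor(blockRatio × n)` bottom-ranked
  features are removed and the accuracy re-estimated. An accuracy at least
  equal to the reference commits the removal and makes this trial the new
  reference (its own averaged importances become the next ranking). A drop
  puts the block back and advances `startingIndex` by the block size, so
  the next trial tests the block ranked just above — the heuristic probes
  progressively better-ranked blocks rather than stalling.
* **Soft-fails and decay.** When `startingIndex` has swept the whole
  ranking, or after `max_consecutive_fails` failures in a row, failed
  trials since the last accepted state are re-examined: one whose accuracy
  drop is within `soft_fail_tolerance` misclassified samples of the
  reference is committed after all, trading a bounded, temporary loss for
  an escape from a local optimum. Only if no trial qualifies is
  `blockRatio` divided by `ratio_divisor`. Termination is guaranteed:
  `blockRatio` decreases geometrically, so `floor(blockRatio × n)` reaches
  zero after finitely many reductions, and every acceptance strictly
  shrinks the feature set.

Accepted states therefore form a chain of disjoint removals, and the final
internal accuracy is at least the initial reference accuracy minus
(number of committed soft-fails) × `tolerance/m` — a regret bound the test
suite asserts on fuzzed runs.

Because the forest is stochastic, `rgife_select()` repeats the whole run
`n_runs` times (default 3) under derived seeds and combines the final sets
with a policy: *Min* and *Max* pick the smallest or largest signature,
*Union* pools them. Union is the most inclusive and, on the synthetic
benchmarks below, the most reliable at covering the planted signal.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | folds per DB-SCV partition |
| `N` | 10 | repeated partitions per estimate; accuracy is averaged over folds, then repetitions |
| `initial_block_ratio` | 0.25 | fraction of current features removed per trial |
| `ratio_divisor` | 4 | geometric decay of the block ratio (use `4/3` for a ×0.75 schedule) |
| `max_consecutive_fails` | 5 | failures in a row that trigger the soft-fail search / decay |
| `soft_fail_tolerance` | 1 sample | tolerated drop, converted to accuracy units as `1/m` |
| `n_trees` | 3000 | ranking-forest size; importance estimates stabilise with many trees |
| `n_runs` | 3 | runs combined by the policy |

The tolerance conversion treats `1/m` as the accuracy value of one
misclassified sample. Fold accuracies are averaged (not pooled), so with
unequal fold sizes one sample is worth slightly more or less than `1/m` in
the average; the DB-SCV balance guarantee (fold sizes differ by at most
one per class) keeps the discrepancy well below the tolerance itself.

"Reduced by a fourth" admits two readings — divide by 4, or multiply by
0.75. The package divides by 4: it gives the heuristic a long block-size-1
refinement phase before termination, which is what produces the very small
final signatures; the ×0.75 schedule remains available through
`ratio_divisor = 4/3`.

The trigger count is *reaching* 5 consecutive failures. The failure
counter resets on any acceptance (normal or soft) and on every block-ratio
reduction; the soft-fail search window extends back to the most recent of
the last accepted state and the last committed soft-fail. Among several
qualifying soft-fails the one with the highest accuracy is committed (ties
to the most recent) — the smallest regret. A committed soft-fail replaces
the pending block-ratio reduction rather than compounding with it, which
keeps larger blocks in play immediately after the escape. If the last
candidate block overshoots the remaining untested features, the partial
block is tested at its reduced size rather than skipped.

## Cross-validation scheme

Stratified cross-validation preserves class proportions but can still
concentrate a cluster of similar samples in one fold, distorting accuracy
estimates on the small cohorts typical of transcriptomics. DB-SCV
counteracts this: within each class it starts at a random sample, assigns
it to fold 1, moves to the nearest unassigned same-class neighbour,
assigns it to fold 2, and so on in rotation; per class the residual
`n mod k` samples go to distinct folds chosen uniformly at random. Nearby
samples end up spread across folds; per class, fold occupancies differ by
at most one. Distances are Euclidean on standardised numeric features plus
a mismatch count on categorical features (the literature specifies no
metric; this is the natural mixed-type choice), and neighbour ties break
to the lowest sample index for reproducibility.

## Classifier backends

The ranking forest is `ranger` with gini (impurity-decrease) importance,
`num.trees = 3000` by default and all other settings at the backend
defaults. Signature evaluation mirrors common practice in the field with
four families: a random forest capped at depth 5 whose prediction is a
majority vote over 10 independently seeded models (the cap counteracts
overfitting on very small signatures), a linear-kernel SVM, Gaussian naive
Bayes and 5-nearest-neighbours. Tree models receive categorical features
ordinally encoded; the margin- and distance-based families receive one-hot
encodings, with dummy levels fixed by the training data. The SVM is run
without internal rescaling (one-hot and binary designs make per-column
rescaling degenerate), and the naive-Bayes class-conditional standard
deviations are floored at `1e-6` so constant columns cannot produce
infinite densities. Every forest prediction is explicitly seeded because
the backend breaks class-vote ties at random.

## Synthetic benchmark generators

The generators reproduce the *structure* of the classic feature-selection
benchmarks — dimensions, relevance composition, class rules — with all
randomness drawn from one seeded stream per call:

* **CorrAL** (32 × 99): class `(f1∧f2)∨(f3∧f4)`; `f5` irrelevant; `f6`
  agrees with the class on exactly 24/32 samples (75%), realised by
  flipping the class bit on exactly 8 rows; 93 random binary decoys. The
  rows enumerate all 2⁵ combinations of `f1..f5`.
* **XOR-100** (50 × 99): class `f1 ⊕ f2`, 97 random decoys; a non-linear
  target no single-feature filter can see.
* **Parity3+3** (64 × 12): parity of three bits, one redundant copy of
  each, six irrelevant bits; rows enumerate all 2⁶ combinations of the
  relevant and first three irrelevant bits. The 3+3+6 split follows the
  dataset's conventional construction.
* **Monk3** (122 × 6): categorical attributes over the standard MONK
  domains, rule `(f5=3 ∧ f4=1) ∨ (f5≠4 ∧ f2≠3)`, 5% of labels flipped
  (`noise = FALSE` disables the flip). The second clause of the rule is
  completed to `f4 = 1` per the standard MONK-3 definition.
* **SD1–SD3** (75 × 4020/4040/4060, three balanced classes): groups of ten
  mutually redundant genes — a group's genes share a class-mean template
  plus Gaussian noise (sd 0.2). Full-class-relevant groups use per-class
  means that are permutations of (0, 2, 4); partial-class-relevant groups
  single out one class (mean 2) against the rest (mean 0); irrelevant
  genes are standard normal. Each group alone separates its target
  contrast, so the optimal signature is one gene per group (2/4/6). The
  source literature defines these data only through group counts and
  redundancy structure; the signal model here is the simplest one
  realising that structure.
* **Microarray** (default 100 samples): per-gene baseline ~ N(7, 1.5) on a
  log2-like scale, `round(pde × n_genes)` genes shifted ±1.5 in the case
  group (half up, half down), within-group noise sd 0.4. The shift/noise
  ratio makes classes cleanly separable from a single marker, matching the
  saturated accuracies such simulations produce. This is a structural
  emulation, not bit-compatible with any external simulator.
* **Madelon-like** (2400 × 500): five coordinates place samples at the 32
  vertices of a ±1 hypercube (classes alternate by vertex parity, 75
  samples per vertex, jitter sd 0.3), 250 Gaussian decoys, 245 random
  linear combinations of the relevant coordinates, 1% of labels flipped.

What the generators do **not** emulate: probe-level noise models,
batch/array effects, correlated irrelevant genes, missing values, or the
exact distributions of the distributed benchmark files. Tests passing on
these data therefore demonstrate the heuristic's behaviour under clean,
known ground truth — not performance on real cohorts.

## Scoring

`success_index()` implements `100 × (Rs/Rt − α·Is/It)`, `α = min(1/2,
Rt/It)`. For families with redundant features (Parity3+3 copies, SD
groups) the redundant features count on the relevant side by default
(`redundant_as_relevant = FALSE` switches this); the SD-specific taxonomy
is kept separate in `score_sd_selection()`, which counts the first
selected gene per group as optimal, further same-group genes as redundant,
and unflagged features as irrelevant. `overlap_metrics()` gives
precision/recall/F of a signature against any user-supplied reference
list, with the recall denominator (`universe_reference_total`) exposed so
the reference can be restricted to features actually present on the
platform.

## Numerical and degenerate-input choices

* Importance ties break by original column position; fold-assignment
  neighbour ties by lowest index; majority-vote ties by class-name order —
  all deterministic.
* The soft-fail comparison adds `1e-9` to the tolerance so a drop of
  exactly one sample survives floating-point rounding of `1/m`.
* A single-feature dataset returns immediately (no block below one feature
  can be removed); single-class training folds raise an error, and the
  DB-SCV balance makes them impossible whenever every class has at least
  `k` samples... classes smaller than `k` are still spread over distinct
  random folds.
* CSV output writes doubles with 17 significant digits, making
  save/load an exact round trip; ARFF I/O delegates to `foreign`.
* Every stochastic step (generators, fold plans, forest fits and
  predictions, run replication) derives its seed from the caller's seed;
  the recorded `cv_seed` of each iteration allows any trajectory entry's
  accuracy to be replayed exactly.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the full algorithm at sizes a
single CPU handles in minutes, chosen as representative rather than
exhaustive: fuzzed soundness runs use ~30-sample, ~15-feature datasets
with 50-tree forests and 3-fold single-repetition estimates; the
microarray end-to-end check uses 2000 genes with 5% differential
expression, 100-tree forests, `k = 5`, `N = 1` and the Union of three
runs, with one DB-SCV fold held out for external evaluation. The shipped
defaults (3000 trees, `k = N = 10`) remain the recommended analysis
setting.

## Known limitations

* Classification only; regression targets are out of scope.
* The heuristic's accuracy criterion is estimated on the same data that
  guides elimination; external validation (held-out folds, as in the
  acceptance script) is the caller's responsibility.
* Very small per-class counts destabilise both the internal accuracy
  estimate and the importance ranking — visible on the SD family, where
  25 samples per class over ~4000 genes make noise genes hard to separate
  from planted ones.
* Column order influences the ranking forest's candidate-feature draws,
  so rankings are reproducible per seed but not invariant under column
  permutation (importance *ties* are, by construction, position-broken).
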