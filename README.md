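# rgife

Minimal biomarker signatures from class-labelled omics matrices by
**ranked-guided iterative feature elimination**.

High-dimensional transcriptomics experiments routinely measure thousands of
genes on a few dozen samples, yet the biological or clinical question —
which handful of genes separates cases from controls? — calls for a small,
verifiable signature. `rgife` addresses this by iteratively discarding
blocks of features that a tree-ensemble ranks as unimportant, keeping a
removal only when the cross-validated accuracy of the model does not drop,
and returning the small surviving set.

## The heuristic

Starting from the full feature set, each trial:

1. estimates a reference accuracy with repeated *k*-fold
   distribution-balanced stratified cross-validation (DB-SCV, which walks a
   nearest-neighbour chain inside every class so similar samples land in
   different folds), and averages the gini-impurity importances of all fold
   forests into a consensus ranking;
2. removes the `blockSize = floor(blockRatio * n)` bottom-ranked features
   (`blockRatio` starts at 0.25) and re-estimates the accuracy;
3. accepts the removal if accuracy did not decrease, otherwise places the
   block back and tries the next block up the ranking (tracked by a
   `startingIndex` offset).

When every feature has been tried, or five consecutive trials have failed,
the trajectory is searched for a *soft-fail* — a failed trial within one
misclassified sample of the reference — which is then accepted
retroactively to escape local optima; if none exists, `blockRatio` is
divided by 4. The run stops when the block size falls below one feature.
Because the base forest is stochastic, three runs are combined by a policy:
**Min** (smallest signature), **Max** (largest) or **Union**.

Selections on synthetic benchmarks are scored with the Success Index

    SI = 100 * (Rs/Rt - alpha * Is/It),   alpha = min(1/2, Rt/It)

where `Rs`/`Rt` are selected/total relevant features and `Is`/`It` the
irrelevant counterparts; 100 is attained exactly when all relevant and no
irrelevant features are chosen.

The package ships seeded generators for the classic feature-selection
benchmarks (CorrAL, XOR-100, Parity3+3, Monk3, SD1–SD3, a two-condition
microarray emulation, a Madelon-like hypercube problem), each with a
ground-truth relevance table, plus a four-classifier evaluation harness
(depth-5 voting random forest, linear SVM, Gaussian naive Bayes, KNN).

## Worked example

```r
library(rgife)

d <- gen_microarray(n_genes = 1000, pde = 0.05, m1 = 25, m2 = 25, seed = 42)
d
#> <rgife_dataset> 50 samples x 1000 features
#> classes: case (25), control (25)
#> ground truth: irrelevant (950), relevant (50)

cfg <- rgife_config(k = 5, N = 2, n_runs = 3,
                    learner = learner_config("ranking_forest", n_trees = 200),
                    seed = 42)
res <- rgife_select(d, cfg, policy = "union")
res$runs[[1]]
#> <rgife_run> 3 features selected, internal accuracy 1.0000
#>   22 iterations: 22 green, 0 blue, 0 red, 0 yellow

res$signature
#> [1] "gene00228" "gene00356" "gene00899" "gene00128" "gene00839" "gene00994"
#> [7] "gene00212" "gene00517" "gene00601"

score_selection(res$signature, d$truth)
#> Success Index: 18.00 (Rs 9/50, Is 0/950, alpha 0.0526)
```

Of 1000 genes (50 truly differentially expressed), the union of three runs
keeps 9 — every one of them a true positive (`Is = 0`), and far fewer than
the 50 planted genes because a couple of strong markers already classify
perfectly. The green/blue/red/yellow tally summarises each iteration:
accepted bottom-block removals, accepted off-bottom removals, failures, and
committed soft-fails. `trajectory_table(res$runs[[1]])` exposes the full
reduction trajectory for plotting.

The same pipeline is available from the shell:

```sh
Rscript inst/scripts/rgife simulate xor100 --seed 1 --out xor.csv --truth truth.csv
Rscript inst/scripts/rgife run --data xor.csv --k 5 --n-reps 1 --trees 100 \
    --runs 3 --policy union --seed 1 --out signature.txt --trajectory traj.csv
Rscript inst/scripts/rgife score --selection signature.txt --truth truth.csv
```

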