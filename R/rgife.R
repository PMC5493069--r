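#' RGIFE configuration
#'
#' Collects the tunable parameters of the ranked-guided iterative feature
#' elimination heuristic. The defaults reproduce the method's standard
#' setting: 10x10 DB-SCV performance estimation, an initial block of 25% of
#' the current features, block ratio divided by 4 at each reduction, the
#' soft-fail search triggered after 5 consecutive failures (or when every
#' feature has been tested), a soft-fail tolerance of one misclassified
#' sample, and three runs per policy.
#'
#' @param k cross-validation folds (default 10).
#' @param N cross-validation repetitions (default 10).
#' @param initial_block_ratio starting fraction of features removed per
#'   trial, in (0, 1] (default 0.25).
#' @param ratio_divisor factor (> 1) dividing the block ratio at each
#'   reduction (default 4; use `4/3` for a gentler x0.75 schedule).
#' @param max_consecutive_fails consecutive failed trials that trigger the
#'   soft-fail search / block-ratio reduction (default 5).
#' @param soft_fail_tolerance tolerated performance drop in misclassified
#'   samples (default 1).
#' @param n_runs independent runs combined by a policy (default 3).
#' @param learner a [learner_config()] for the internal ranking model.
#' @param seed integer master seed.
#' @return An object of class `rgife_config`.
#' @export
rgife_config <- function(k = 10, N = 10, initial_block_ratio = 0.25,
                         ratio_divisor = 4, max_consecutive_fails = 5,
                         soft_fail_tolerance = 1, n_runs = 3,
                         learner = learner_config("ranking_forest"),
                         seed = 1) {
  if (!(initial_block_ratio > 0 && initial_block_ratio <= 1)) {
    stop("initial_block_ratio must be in (0, 1]")
  }
  if (ratio_divisor <= 1) stop("ratio_divisor must be > 1")
  if (max_consecutive_fails < 1) stop("max_consecutive_fails must be >= 1")
  if (soft_fail_tolerance < 0) stop("soft_fail_tolerance must be >= 0")
  if (n_runs < 1) stop("n_runs must be >= 1")
  structure(list(k = k, N = N, initial_block_ratio = initial_block_ratio,
                 ratio_divisor = ratio_divisor,
                 max_consecutive_fails = max_consecutive_fails,
                 soft_fail_tolerance = soft_fail_tolerance,
                 n_runs = n_runs, learner = learner, seed = seed),
            class = "rgife_config")
}

#' Select a block of bottom-ranked features
#'
#' Returns the `block_size` features occupying the rank positions counted
#' from the bottom of the ranking, after skipping the bottom
#' `starting_index` positions (the features already tested and placed back).
#'
#' @param ranking a [ranked_importance()].
#' @param starting_index offset from the bottom of the rank (>= 0).
#' @param block_size number of features in the block (>= 1).
#' @return character vector of feature names.
#' @export
select_block <- function(ranking, starting_index, block_size) {
  n <- length(ranking$order)
  if (starting_index < 0) stop("starting_index must be >= 0")
  if (block_size < 1) stop("block_size must be >= 1")
  if (starting_index + block_size > n) {
    stop("block [", starting_index, ", ", starting_index + block_size,
         ") exceeds the ", n, " ranked features")
  }
  ranking$order[(n - starting_index - block_size + 1):(n - starting_index)]
}

#' Search the trajectory for an acceptable soft-fail
#'
#' Scans the failed trials recorded after `anchor` (the reference iteration
#' or the last committed soft-fail, whichever is more recent) for one whose
#' performance drop relative to its reference is within the tolerance of
#' `tolerance` misclassified samples, i.e. `tolerance / m` in mean-accuracy
#' units. Among several qualifying trials the one with the highest
#' performance is returned, ties going to the most recent.
#'
#' @param trajectory list of iteration records (see [run_rgife()]).
#' @param anchor index into `trajectory` after which to search (0 scans the
#'   whole trajectory).
#' @param tolerance tolerated drop in misclassified samples.
#' @param m total number of samples.
#' @return The qualifying record (with its position in `$trajectory_index`),
#'   or `NULL` if none qualifies.
#' @export
find_soft_fail <- function(trajectory, anchor, tolerance, m) {
  if (length(trajectory) == 0) return(NULL)
  best <- NULL
  window <- seq_along(trajectory)
  window <- window[window > anchor]
  for (i in window) {
    rec <- trajectory[[i]]
    if (rec$status != "fail") next
    drop <- rec$reference_performance - rec$performance
    if (drop <= tolerance / m + 1e-9) {  # guard against float rounding of 1/m
      if (is.null(best) || rec$performance >= best$performance) {
        best <- rec
        best$trajectory_index <- i
      }
    }
  }
  best
}

new_record <- function(index, status, removed, performance,
                       reference_performance, block_ratio, block_size,
                       starting_index, surviving_count, cv_seed,
                       importances = NULL) {
  list(index = index, status = status, removed_features = removed,
       performance = performance,
       reference_performance = reference_performance,
       block_ratio = block_ratio, block_size = block_size,
       starting_index = starting_index, surviving_count = surviving_count,
       cv_seed = cv_seed, importances = importances)
}

#' Run the RGIFE heuristic
#'
#' Iteratively removes blocks of bottom-ranked features while the estimated
#' predictive performance does not degrade. Each iteration: (1) the
#' reference performance and consensus gini ranking come from the currently
#' accepted feature set; (2) the `block_size = floor(block_ratio * n)`
#' features ranked lowest (offset upward by `starting_index`) are removed
#' and performance is re-estimated; (3) if the new performance is at least
#' the reference, the block is permanently eliminated and this trial becomes
#' the new reference; otherwise the block is placed back and the next block
#' up the rank is tried. When every feature has been tested, or after
#' `max_consecutive_fails` consecutive failures, the trajectory is first
#' searched for a soft-fail (a failed trial within one misclassified sample
#' of the reference, which is then committed); if none qualifies the block
#' ratio is divided by `ratio_divisor`. The run terminates when the block
#' size falls below one feature.
#'
#' @param dataset an [rgife_dataset()].
#' @param config an [rgife_config()].
#' @param seed integer seed overriding `config$seed` (optional).
#' @param verbose print one line per iteration.
#' @return An object of class `rgife_run`: `final_signature` (character),
#'   `final_performance`, `seed` and `trajectory`, a list of iteration
#'   records with fields `index`, `status` (`success_bottom`,
#'   `success_offset`, `fail`, `soft_fail_accept`), `removed_features`,
#'   `performance`, `reference_performance`, `block_ratio`, `block_size`,
#'   `starting_index`, `surviving_count` and `cv_seed` (the seed that
#'   reproduces the trial's performance estimate).
#' @export
run_rgife <- function(dataset, config = rgife_config(), seed = NULL,
                      verbose = FALSE) {
  validate_dataset(dataset)
  if (is.null(seed)) seed <- config$seed
  m <- n_samples(dataset)
  tol_acc <- config$soft_fail_tolerance / m
  say <- function(...) if (verbose) message(sprintf(...))

  ref_features <- feature_names(dataset)
  ref_seed <- derive_seed(seed, 0L)
  ref_est <- estimate_performance(dataset, ref_features, config$learner,
                                  k = config$k, N = config$N,
                                  seed = ref_seed, importance = TRUE)
  ref_perf <- ref_est$mean_accuracy
  ref_rank <- ranked_importance(ref_est$importances)
  say("iteration 0: reference accuracy %.4f on %d features",
      ref_perf, length(ref_features))

  block_ratio <- config$initial_block_ratio
  starting_index <- 0L
  fails <- 0L
  anchor <- 0L
  trajectory <- list()
  iter <- 0L

  repeat {
    n <- length(ref_features)
    block_size <- floor(block_ratio * n)
    if (block_size < 1) break
    actual_size <- min(block_size, n - starting_index)
    block <- select_block(ref_rank, starting_index, actual_size)
    candidate <- setdiff(ref_features, block)
    iter <- iter + 1L
    cv_seed <- derive_seed(seed, iter)
    est <- estimate_performance(dataset, candidate, config$learner,
                                k = config$k, N = config$N,
                                seed = cv_seed, importance = TRUE)
    perf <- est$mean_accuracy
    if (perf >= ref_perf) {
      status <- if (starting_index == 0L) "success_bottom" else "success_offset"
      trajectory[[length(trajectory) + 1L]] <-
        new_record(iter, status, block, perf, ref_perf, block_ratio,
                   actual_size, starting_index, length(candidate), cv_seed)
      ref_features <- candidate
      ref_perf <- perf
      ref_rank <- ranked_importance(est$importances)
      starting_index <- 0L
      fails <- 0L
      anchor <- length(trajectory)
      say("iteration %d: %s, accuracy %.4f, %d features survive",
          iter, status, perf, length(ref_features))
    } else {
      trajectory[[length(trajectory) + 1L]] <-
        new_record(iter, "fail", block, perf, ref_perf, block_ratio,
                   actual_size, starting_index, length(ref_features), cv_seed,
                   importances = est$importances)
      fails <- fails + 1L
      starting_index <- starting_index + actual_size
      say("iteration %d: fail (%.4f < %.4f), startingIndex -> %d",
          iter, perf, ref_perf, starting_index)
      all_tested <- starting_index >= n
      if (fails >= config$max_consecutive_fails || all_tested) {
        sf <- find_soft_fail(trajectory, anchor,
                             config$soft_fail_tolerance, m)
        if (!is.null(sf)) {
          iter <- iter + 1L
          trajectory[[length(trajectory) + 1L]] <-
            new_record(iter, "soft_fail_accept", sf$removed_features,
                       sf$performance, ref_perf, block_ratio,
                       sf$block_size, sf$starting_index,
                       length(ref_features) - length(sf$removed_features),
                       sf$cv_seed)
          ref_features <- setdiff(ref_features, sf$removed_features)
          ref_perf <- sf$performance
          ref_rank <- ranked_importance(
            sf$importances[ref_features])
          starting_index <- 0L
          fails <- 0L
          anchor <- length(trajectory)
          say("iteration %d: soft-fail committed (accuracy %.4f), %d features survive",
              iter, ref_perf, length(ref_features))
        } else {
          block_ratio <- block_ratio / config$ratio_divisor
          starting_index <- 0L
          fails <- 0L
          say("no soft-fail found: blockRatio -> %.4g", block_ratio)
        }
      }
    }
  }
  structure(list(final_signature = ref_features,
                 final_performance = ref_perf,
                 trajectory = trajectory,
                 seed = seed),
            class = "rgife_run")
}

#' @export
print.rgife_run <- function(x, ...) {
  st <- table(factor(vapply(x$trajectory, `[[`, "", "status"),
                     levels = c("success_bottom", "success_offset",
                                "fail", "soft_fail_accept")))
  cat(sprintf("<rgife_run> %d features selected, internal accuracy %.4f\n",
              length(x$final_signature), x$final_performance))
  cat(sprintf("  %d iterations: %d green, %d blue, %d red, %d yellow\n",
              length(x$trajectory), st[1], st[2], st[3], st[4]))
  invisible(x)
}

#' Combine several runs into one signature
#'
#' `min` / `max` return the final signature of the run with the smallest /
#' largest signature (ties to the earliest run); `union` returns the union
#' of all final signatures.
#'
#' @param runs non-empty list of `rgife_run` objects.
#' @param policy `"union"`, `"min"` or `"max"`.
#' @return character vector of feature names.
#' @export
apply_policy <- function(runs, policy = c("union", "min", "max")) {
  policy <- match.arg(policy)
  if (length(runs) == 0) stop("'runs' must contain at least one run")
  sigs <- lapply(runs, function(r) {
    if (inherits(r, "rgife_run")) r$final_signature else r
  })
  switch(policy,
         union = Reduce(union, sigs),
         min = sigs[[which.min(lengths(sigs))]],
         max = sigs[[which.max(lengths(sigs))]])
}

#' Multi-run signature selection
#'
#' Runs the heuristic `config$n_runs` times with seeds derived from the
#' master seed and combines the final signatures with the requested policy.
#'
#' @inheritParams run_rgife
#' @param policy `"union"`, `"min"` or `"max"`.
#' @return A list with `signature`, `policy`, and `runs` (the individual
#'   `rgife_run` objects).
#' @export
rgife_select <- function(dataset, config = rgife_config(),
                         policy = c("union", "min", "max"),
                         verbose = FALSE) {
  policy <- match.arg(policy)
  runs <- lapply(seq_len(config$n_runs), function(r) {
    run_rgife(dataset, config, seed = derive_seed(config$seed, 104729L * r),
              verbose = verbose)
  })
  list(signature = apply_policy(runs, policy), policy = policy, runs = runs)
}

#' Tabulate a run's trajectory
#'
#' @param run an `rgife_run`, or a list of them.
#' @return data.frame with one row per iteration record: run, index, status,
#'   block_ratio, block_size, starting_index, performance, reference,
#'   surviving_count and the removed features semicolon-joined.
#' @export
trajectory_table <- function(run) {
  runs <- if (inherits(run, "rgife_run")) list(run) else run
  rows <- list()
  for (ri in seq_along(runs)) {
    for (rec in runs[[ri]]$trajectory) {
      rows[[length(rows) + 1L]] <- data.frame(
        run = ri, index = rec$index, status = rec$status,
        block_ratio = rec$block_ratio, block_size = rec$block_size,
        starting_index = rec$starting_index,
        performance = rec$performance,
        reference = rec$reference_performance,
        surviving_count = rec$surviving_count,
        removed = paste(rec$removed_features, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(run = integer(), index = integer(),
                      status = character(), block_ratio = numeric(),
                      block_size = integer(), starting_index = integer(),
                      performance = numeric(), reference = numeric(),
                      surviving_count = integer(), removed = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
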