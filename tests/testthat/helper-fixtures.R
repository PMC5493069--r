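# Shared fixtures: everything is generated in code, seeded for determinism.

small_forest <- function(n_trees = 50) {
  learner_config("ranking_forest", n_trees = n_trees)
}

# label equals the binary feature "key" exactly; all other features are noise
make_single_feature_dataset <- function(m = 50, p = 20, seed = 1) {
  set.seed(seed)
  key <- sample(rep(0:1, length.out = m))
  noise <- matrix(rnorm(m * (p - 1)), m)
  colnames(noise) <- sprintf("n%02d", seq_len(p - 1))
  rgife_dataset(data.frame(key = key, noise), key)
}

# small two-class dataset with a few informative and several noise features
make_fuzz_dataset <- function(seed) {
  set.seed(seed)
  m <- sample(21:36, 1)
  p_noise <- sample(6:14, 1)
  y <- sample(rep(0:1, length.out = m))
  informative <- sapply(1:2, function(i) y * runif(1, 1, 2) + rnorm(m, sd = 0.6))
  colnames(informative) <- paste0("sig", 1:2)
  noise <- matrix(rnorm(m * p_noise), m)
  colnames(noise) <- sprintf("nz%02d", seq_len(p_noise))
  rgife_dataset(data.frame(informative, noise), y)
}

# split an rgife_dataset by row indices into train/test datasets
split_rows <- function(d, test_idx) {
  train_idx <- setdiff(seq_len(n_samples(d)), test_idx)
  list(train = rgife_dataset(d$x[train_idx, , drop = FALSE],
                             d$labels[train_idx], d$truth),
       test = rgife_dataset(d$x[test_idx, , drop = FALSE],
                            d$labels[test_idx], d$truth))
}

# reconstruct the accepted feature set before every record and replay
# performance estimates for the records at positions `at`
replay_records <- function(run, dataset, config, at) {
  current <- feature_names(dataset)
  out <- list()
  for (i in seq_along(run$trajectory)) {
    rec <- run$trajectory[[i]]
    candidate <- setdiff(current, rec$removed_features)
    if (i %in% at) {
      est <- estimate_performance(dataset, candidate, config$learner,
                                  k = config$k, N = config$N,
                                  seed = rec$cv_seed)
      out[[length(out) + 1L]] <- c(recorded = rec$performance,
                                   replayed = est$mean_accuracy)
    }
    if (rec$status != "fail") current <- candidate
  }
  out
}
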