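#' Distribution-balanced stratified cross-validation fold assignment
#'
#' Builds `k` disjoint folds covering all samples. Within every class the
#' assignment walks a nearest-neighbour chain: starting from a random sample,
#' the current sample is assigned to folds 1..k in rotation and the walk
#' moves to its nearest unassigned same-class neighbour, so close-by samples
#' land in different folds. Once fewer than `k` same-class samples remain,
#' these residuals are placed in distinct folds chosen uniformly at random.
#' Per class, fold occupancies therefore differ by at most one.
#'
#' Distances are Euclidean on standardised numeric features plus a mismatch
#' count (Hamming) on categorical features; neighbour ties go to the lowest
#' sample index.
#'
#' @param dataset an [rgife_dataset()].
#' @param k number of folds, `2 <= k <= n_samples(dataset)`.
#' @param seed integer seed for the chain starts and residual placement.
#' @return An object of class `fold_plan`: list with `k` and `folds`, a list
#'   of `k` integer vectors of sample indices.
#' @export
dbscv_folds <- function(dataset, k, seed = 1) {
  m <- n_samples(dataset)
  if (k < 2) stop("k must be at least 2")
  if (k > m) stop("k (", k, ") cannot exceed the number of samples (", m, ")")
  dm <- mixed_distance(dataset$x)
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in levels(dataset$labels)) {
      idx <- which(dataset$labels == cl)
      n_c <- length(idx)
      n_res <- n_c %% k
      n_chain <- n_c - n_res
      assigned <- logical(n_c)
      if (n_chain > 0) {
        cur <- sample.int(n_c, 1)
        for (step in seq_len(n_chain)) {
          assigned[cur] <- TRUE
          f <- (step - 1L) %% k + 1L
          folds[[f]] <- c(folds[[f]], idx[cur])
          if (step < n_chain) {
            open <- which(!assigned)
            d <- dm[idx[cur], idx[open]]
            cur <- open[which.min(d)]  # which.min takes the lowest index on ties
          }
        }
      }
      residual <- idx[!assigned]
      if (length(residual) > 0) {
        for (j in seq_along(residual)) {
          # distinct folds, uniformly without replacement
          if (j == 1) res_folds <- sample.int(k, length(residual))
          folds[[res_folds[j]]] <- c(folds[[res_folds[j]]], residual[j])
        }
      }
    }
  })
  structure(list(k = k, folds = lapply(folds, sort)), class = "fold_plan")
}

# Euclidean distance on standardised numeric columns + Hamming on factors.
mixed_distance <- function(x) {
  num <- vapply(x, is.numeric, logical(1))
  m <- nrow(x)
  total <- matrix(0, m, m)
  if (any(num)) {
    xs <- scale(as.matrix(x[, num, drop = FALSE]))
    xs[is.nan(xs)] <- 0  # constant columns carry no distance
    total <- total + as.matrix(stats::dist(xs))
  }
  if (any(!num)) {
    for (j in which(!num)) {
      total <- total + outer(x[[j]], x[[j]], FUN = "!=")
    }
  }
  total
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d; fold sizes: %s\n", x$k,
              paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}

#' Repeated DB-SCV performance estimate
#'
#' Estimates the predictive accuracy of a learner on a feature subset by `N`
#' repetitions of `k`-fold DB-SCV: in each repetition the model is trained on
#' `k - 1` folds and predicts the held-out fold; fold accuracies are averaged
#' into a repetition accuracy and repetition accuracies into the mean.
#' When the learner is the ranking forest, the gini importances of all
#' `k * N` fold models are averaged into one consensus ranking vector.
#'
#' @param dataset an [rgife_dataset()].
#' @param feature_subset character vector of feature names to use (non-empty).
#' @param learner a [learner_config()].
#' @param k folds per repetition (default 10).
#' @param N repetitions (default 10).
#' @param seed integer seed; drives fold construction and model fits.
#' @param importance also return averaged feature importances (ranking forest
#'   only).
#' @return An object of class `performance_estimate` with `mean_accuracy`,
#'   `per_repetition_accuracies`, `n_repetitions`, `total_samples` and, if
#'   requested, `importances` (named, summing to 1).
#' @export
estimate_performance <- function(dataset, feature_subset, learner,
                                 k = 10, N = 10, seed = 1,
                                 importance = FALSE) {
  if (length(feature_subset) == 0) stop("feature_subset must be non-empty")
  if (k < 1 || N < 1) stop("k and N must be >= 1")
  sub <- subset_features(dataset, feature_subset)
  rep_acc <- numeric(N)
  imp_sum <- if (importance) {
    stats::setNames(numeric(n_features(sub)), feature_names(sub))
  } else NULL
  n_models <- 0
  for (r in seq_len(N)) {
    plan <- dbscv_folds(sub, k, seed = derive_seed(seed, 2L * r))
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      test_idx <- plan$folds[[f]]
      train_idx <- setdiff(seq_len(n_samples(sub)), test_idx)
      fit <- tryCatch(
        fit_learner(learner, sub$x[train_idx, , drop = FALSE],
                    droplevels(dataset$labels[train_idx]),
                    seed = derive_seed(seed, 2L * (r * k + f) + 1L)),
        error = function(e) {
          stop("learner failed in repetition ", r, ", fold ", f, ": ",
               conditionMessage(e), call. = FALSE)
        })
      pred <- predict_learner(fit, sub$x[test_idx, , drop = FALSE])
      fold_acc[f] <- mean(as.character(pred) ==
                            as.character(dataset$labels[test_idx]))
      if (importance) {
        imp <- fit$importances
        if (is.null(imp)) stop("learner '", learner$family,
                               "' provides no importances")
        s <- sum(imp)
        if (s > 0) imp <- imp / s
        imp_sum <- imp_sum + imp[feature_names(sub)]
        n_models <- n_models + 1
      }
    }
    rep_acc[r] <- mean(fold_acc)
  }
  out <- list(mean_accuracy = mean(rep_acc),
              per_repetition_accuracies = rep_acc,
              n_repetitions = N,
              total_samples = n_samples(dataset))
  if (importance) {
    imp <- imp_sum / n_models
    if (sum(imp) > 0) imp <- imp / sum(imp)
    out$importances <- imp
  }
  structure(out, class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("<performance_estimate> mean accuracy %.4f over %d repetition(s)\n",
              x$mean_accuracy, x$n_repetitions))
  invisible(x)
}
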