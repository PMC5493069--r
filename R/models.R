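#' Learner configuration
#'
#' Describes one of the classifier families used by the package: the
#' heuristic's internal ranking forest (gini-impurity importances, 3000 trees
#' by default), the depth-limited evaluation forest (depth 5, majority vote
#' over 10 models), a linear-kernel SVM, Gaussian naive Bayes, and K-nearest
#' neighbours (k = 5). Tree models see categorical features ordinally
#' encoded; SVM/NB/KNN see them one-hot encoded.
#'
#' @param family one of `"ranking_forest"`, `"eval_forest"`, `"linear_svm"`,
#'   `"gaussian_nb"`, `"knn"`.
#' @param n_trees trees in the ranking forest (default 3000).
#' @param max_depth depth cap of the evaluation forest (default 5).
#' @param vote_models models in the evaluation forest's majority vote
#'   (default 10).
#' @param mtry candidate features per split in the ranking forest; `NULL`
#'   (default) uses the backend's default (square root of the feature
#'   count).
#' @return An object of class `learner_config`.
#' @export
learner_config <- function(family = c("ranking_forest", "eval_forest",
                                      "linear_svm", "gaussian_nb", "knn"),
                           n_trees = 3000, max_depth = 5, vote_models = 10,
                           mtry = NULL) {
  family <- match.arg(family)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (vote_models < 1) stop("vote_models must be >= 1")
  structure(list(family = family, n_trees = n_trees, max_depth = max_depth,
                 vote_models = vote_models, mtry = mtry),
            class = "learner_config")
}

# ---- encodings ------------------------------------------------------------

# ordinal: factors -> integer codes (tree models)
encode_ordinal <- function(x) {
  out <- lapply(x, function(col) if (is.factor(col)) as.integer(col) else col)
  mat <- do.call(cbind, out)
  colnames(mat) <- names(x)
  mat
}

# one-hot against reference levels taken from training data (margin models)
one_hot_levels <- function(x) {
  lapply(x, function(col) if (is.factor(col)) levels(col) else NULL)
}

encode_one_hot <- function(x, ref_levels) {
  cols <- list()
  for (nm in names(ref_levels)) {
    col <- x[[nm]]
    lv <- ref_levels[[nm]]
    if (is.null(lv)) {
      cols[[nm]] <- as.numeric(col)
    } else {
      for (l in lv) {
        cols[[paste0(nm, "=", l)]] <- as.numeric(as.character(col) == l)
      }
    }
  }
  mat <- do.call(cbind, cols)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(x))
  colnames(mat) <- names(cols)
  mat
}

# ---- fit / predict --------------------------------------------------------

# Internal learner contract: fit_learner() returns a list with $family,
# $feature_names, $predict_fun-relevant state and, for the ranking forest,
# named $importances. predict_learner() dispatches on $family.
fit_learner <- function(config, x, y, seed = 1) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("training data contains a single class")
  fnames <- names(x)
  fit <- switch(
    config$family,
    ranking_forest = {
      m <- ranger::ranger(x = encode_ordinal(x), y = y,
                          num.trees = config$n_trees,
                          importance = "impurity",
                          mtry = if (!is.null(config$mtry)) {
                            min(config$mtry, ncol(x))
                          },
                          num.threads = 1, seed = seed)
      imp <- m$variable.importance[fnames]
      imp[is.na(imp)] <- 0
      list(model = m, importances = stats::setNames(pmax(imp, 0), fnames))
    },
    eval_forest = {
      models <- lapply(seq_len(config$vote_models), function(i) {
        ranger::ranger(x = encode_ordinal(x), y = y,
                       num.trees = 500, max.depth = config$max_depth,
                       num.threads = 1, seed = derive_seed(seed, i))
      })
      list(models = models)
    },
    linear_svm = {
      lv <- one_hot_levels(x)
      xm <- encode_one_hot(x, lv)
      list(model = e1071::svm(xm, y, kernel = "linear", scale = FALSE),
           ref_levels = lv)
    },
    gaussian_nb = {
      lv <- one_hot_levels(x)
      xm <- encode_one_hot(x, lv)
      m <- e1071::naiveBayes(as.data.frame(xm), y)
      # floor the per-class sd so constant columns cannot yield NaN densities
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6)
        tb
      })
      list(model = m, ref_levels = lv)
    },
    knn = {
      lv <- one_hot_levels(x)
      list(train_x = encode_one_hot(x, lv), train_y = y, ref_levels = lv)
    })
  c(fit, list(family = config$family, feature_names = fnames,
              levels = levels(y), seed = seed))
}

predict_learner <- function(fit, x) {
  missing <- setdiff(fit$feature_names, names(x))
  extra <- setdiff(names(x), fit$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature mismatch between model and test data",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")))
  }
  x <- x[, fit$feature_names, drop = FALSE]
  if (nrow(x) == 0) return(factor(character(), levels = fit$levels))
  switch(
    fit$family,
    # predictions are explicitly seeded: ranger breaks class-vote ties at
    # random, and an unseeded predict() would not be reproducible
    ranking_forest = stats::predict(fit$model, data = encode_ordinal(x),
                                    seed = fit$seed,
                                    num.threads = 1)$predictions,
    eval_forest = {
      xm <- encode_ordinal(x)
      votes <- sapply(seq_along(fit$models), function(i) {
        as.character(stats::predict(fit$models[[i]], data = xm,
                                    seed = derive_seed(fit$seed, i),
                                    num.threads = 1)$predictions)
      })
      if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
      majority <- apply(votes, 1, function(v) {
        tb <- table(v)
        names(tb)[which.max(tb)]  # ties: first alphabetically, deterministic
      })
      factor(majority, levels = fit$levels)
    },
    linear_svm = stats::predict(fit$model, encode_one_hot(x, fit$ref_levels)),
    gaussian_nb = stats::predict(
      fit$model, as.data.frame(encode_one_hot(x, fit$ref_levels))),
    knn = with_seed(fit$seed, {
      class::knn(fit$train_x, encode_one_hot(x, fit$ref_levels),
                 fit$train_y, k = min(5, nrow(fit$train_x)))
    }))
}

#' Train the ranking forest and rank the features
#'
#' Fits a gini-impurity random forest on the dataset and derives the
#' feature ranking used to guide block elimination: per-feature importance is
#' the sample-weighted impurity decrease summed over all splits, normalised
#' to sum to one whenever any split occurred.
#'
#' @param train an [rgife_dataset()] with at least two classes.
#' @param config a [learner_config()] with `family = "ranking_forest"`.
#' @param seed integer seed for the forest.
#' @return A list with `model` (class `rgife_model`, usable with
#'   [predict.rgife_model()]) and `ranking`, a [ranked_importance()].
#' @export
train_ranking_model <- function(train, config = learner_config(), seed = 1) {
  if (config$family != "ranking_forest") {
    stop("config$family must be 'ranking_forest'")
  }
  fit <- fit_learner(config, train$x, train$labels, seed = seed)
  imp <- fit$importances
  if (sum(imp) > 0) imp <- imp / sum(imp)
  list(model = structure(fit, class = "rgife_model"),
       ranking = ranked_importance(imp))
}

#' Ranked feature importances
#'
#' @param importances named non-negative numeric vector of per-feature
#'   scores.
#' @return An object of class `ranked_importance` with `importances` and
#'   `order`, the feature names sorted by decreasing importance (ties broken
#'   by original position).
#' @export
ranked_importance <- function(importances) {
  if (is.null(names(importances))) stop("importances must be named")
  if (any(importances < 0)) stop("importances must be non-negative")
  ord <- names(importances)[order(-importances, seq_along(importances))]
  structure(list(importances = importances, order = ord),
            class = "ranked_importance")
}

#' @export
print.ranked_importance <- function(x, ...) {
  top <- utils::head(x$order, 5)
  cat(sprintf("<ranked_importance> %d features; top: %s\n",
              length(x$order), paste(top, collapse = ", ")))
  invisible(x)
}

#' Predict class labels with a fitted model
#'
#' @param object an `rgife_model` from [train_ranking_model()].
#' @param newdata an [rgife_dataset()] (or bare data.frame) whose features
#'   match the model's training features exactly.
#' @param ... unused.
#' @return factor of predicted labels, one per test sample.
#' @export
predict.rgife_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "rgife_dataset")) newdata$x else newdata
  predict_learner(unclass(object), x)
}

#' Evaluate a signature with several classifier families
#'
#' Trains each requested classifier family on the training set restricted to
#' the signature and reports its accuracy on the test set. The evaluation
#' forest (`"eval_forest"`) is a depth-capped random forest whose prediction
#' is a majority vote over `vote_models` independently seeded models.
#'
#' @param train,test [rgife_dataset()]s sharing the signature's features.
#' @param signature non-empty character vector of feature names.
#' @param families classifier families to evaluate (see [learner_config()]).
#' @param seed integer seed.
#' @return named numeric vector of test-set accuracies, one per family.
#' @export
evaluate_signature <- function(train, test, signature,
                               families = c("eval_forest", "linear_svm",
                                            "gaussian_nb", "knn"),
                               seed = 1) {
  if (length(signature) == 0) stop("signature must be non-empty")
  tr <- subset_features(train, signature)
  te <- subset_features(test, signature)
  acc <- vapply(families, function(fam) {
    cfg <- learner_config(fam)
    fit <- fit_learner(cfg, tr$x, tr$labels, seed = derive_seed(seed, 1L))
    pred <- predict_learner(fit, te$x)
    mean(as.character(pred) == as.character(te$labels))
  }, numeric(1))
  stats::setNames(acc, families)
}
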