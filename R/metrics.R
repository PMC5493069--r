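#' Success Index of a feature selection
#'
#' `100 * (Rs/Rt - alpha * Is/It)` with `alpha = min(1/2, Rt/It)`: rewards
#' selecting relevant features and penalises selecting irrelevant ones. The
#' maximum, 100, is attained exactly when all relevant and no irrelevant
#' features are selected.
#'
#' @param Rs relevant features selected (0 <= Rs <= Rt).
#' @param Rt total relevant features (>= 1).
#' @param Is irrelevant features selected (0 <= Is <= It).
#' @param It total irrelevant features (>= 1).
#' @return An object of class `selection_score` with the counts, `alpha` and
#'   `success_index`.
#' @export
success_index <- function(Rs, Rt, Is, It) {
  if (Rt < 1) stop("Rt must be >= 1")
  if (It < 1) stop("It must be >= 1")
  if (Rs < 0 || Rs > Rt) stop("Rs must satisfy 0 <= Rs <= Rt")
  if (Is < 0 || Is > It) stop("Is must satisfy 0 <= Is <= It")
  alpha <- min(0.5, Rt / It)
  structure(list(Rs = Rs, Rt = Rt, Is = Is, It = It, alpha = alpha,
                 success_index = 100 * (Rs / Rt - alpha * Is / It)),
            class = "selection_score")
}

#' @export
print.selection_score <- function(x, ...) {
  cat(sprintf("Success Index: %.2f (Rs %d/%d, Is %d/%d, alpha %.4f)\n",
              x$success_index, x$Rs, x$Rt, x$Is, x$It, x$alpha))
  invisible(x)
}

#' Success Index of a selection against a ground-truth table
#'
#' Counts relevant/irrelevant selections from a truth table (as produced by
#' the synthetic generators) and evaluates [success_index()].
#'
#' @param selection character vector of selected feature names.
#' @param truth data.frame with `feature` and `flag` columns.
#' @param redundant_as_relevant count `redundant`-flagged features on the
#'   relevant side (default `TRUE`).
#' @return A `selection_score`.
#' @export
score_selection <- function(selection, truth, redundant_as_relevant = TRUE) {
  unknown <- setdiff(selection, truth$feature)
  if (length(unknown) > 0) {
    stop("selection contains unknown feature(s): ",
         paste(unknown, collapse = ", "))
  }
  rel_flags <- if (redundant_as_relevant) c("relevant", "redundant") else "relevant"
  rel <- truth$feature[truth$flag %in% rel_flags]
  irr <- truth$feature[!(truth$flag %in% rel_flags)]
  success_index(Rs = length(intersect(selection, rel)), Rt = length(rel),
                Is = length(intersect(selection, irr)), It = length(irr))
}

#' Score a selection on an SD dataset
#'
#' Classifies every selected feature under the SD taxonomy: the first
#' selected gene of each relevant group counts towards the optimal subset
#' (one gene per group; 2, 4 or 6 groups for SD1-SD3), further genes from an
#' already represented group are redundant, and features flagged irrelevant
#' are irrelevant.
#'
#' @param selection character vector of selected feature names.
#' @param truth truth table with `feature`, `flag`, `group` columns (see
#'   [gen_sd()]).
#' @return An object of class `sd_score` with counts `selected`,
#'   `optimal_hit`, `redundant` and `irrelevant`.
#' @export
score_sd_selection <- function(selection, truth) {
  unknown <- setdiff(selection, truth$feature)
  if (length(unknown) > 0) {
    stop("selection contains unknown feature(s): ",
         paste(unknown, collapse = ", "))
  }
  groups_seen <- character()
  optimal_hit <- 0L
  redundant <- 0L
  irrelevant <- 0L
  info <- truth[match(selection, truth$feature), , drop = FALSE]
  for (i in seq_along(selection)) {
    if (info$flag[i] != "relevant" || is.na(info$group[i])) {
      irrelevant <- irrelevant + 1L
    } else if (info$group[i] %in% groups_seen) {
      redundant <- redundant + 1L
    } else {
      groups_seen <- c(groups_seen, info$group[i])
      optimal_hit <- optimal_hit + 1L
    }
  }
  structure(list(selected = length(selection), optimal_hit = optimal_hit,
                 redundant = redundant, irrelevant = irrelevant),
            class = "sd_score")
}

#' @export
print.sd_score <- function(x, ...) {
  cat(sprintf("SD score: %d selected; OPT %d, redundant %d, irrelevant %d\n",
              x$selected, x$optimal_hit, x$redundant, x$irrelevant))
  invisible(x)
}

#' Set-overlap precision, recall and F-measure
#'
#' Generic overlap of a signature with a reference feature list: precision
#' is the fraction of signature members found in the reference; recall is
#' the overlap divided by `universe_reference_total`, the number of
#' reference features present in the original attribute universe; F is
#' their harmonic mean (0 when both are 0).
#'
#' @param signature non-empty character vector.
#' @param reference character vector of reference features.
#' @param universe_reference_total total reference features in the universe
#'   (defaults to `length(unique(reference))`).
#' @return list with `precision`, `recall`, `f_measure` and `overlap`.
#' @export
overlap_metrics <- function(signature, reference,
                            universe_reference_total = length(unique(reference))) {
  if (length(signature) == 0) stop("signature must be non-empty")
  ov <- length(intersect(signature, reference))
  if (universe_reference_total < ov) {
    stop("universe_reference_total cannot be smaller than the overlap")
  }
  precision <- ov / length(unique(signature))
  recall <- if (universe_reference_total > 0) {
    ov / universe_reference_total
  } else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f_measure = f, overlap = ov)
}
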