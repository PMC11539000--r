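#' Leakage-free grouped train/validation/test split
#'
#' Partitions pairs so that every pair sharing one basis entity (the siRNA
#' under `basis = "sirna"`, the mRNA under `basis = "mrna"`) lands in the
#' same subset — the entity sets of train/validation/test are disjoint by
#' construction, so no test-time entity is ever seen in training. Entities
#' are shuffled by the seed and assigned greedily to the subset whose pair
#' count is furthest below its target, which approximates the requested
#' ratio as closely as grouped assignment allows.
#'
#' @param pairs Pair tibble or [sirna_dataset()].
#' @param basis `"sirna"` or `"mrna"`.
#' @param ratio Train/validation/test proportions, summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed for the entity shuffle.
#' @return A `split_result`: list with `train_ids`, `val_ids`, `test_ids`
#'   (pair ids), `basis`, `seed`, `ratio`.
#' @export
grouped_split <- function(pairs, basis = c("sirna", "mrna"),
                          ratio = c(0.70, 0.15, 0.15), seed = 1L) {
  if (inherits(pairs, "sirna_dataset")) pairs <- pairs$pairs
  basis <- match.arg(basis)
  if (length(ratio) != 3 || any(ratio < 0) || abs(sum(ratio) - 1) > 1e-9) {
    abort("ratio must be three non-negative proportions summing to 1",
          class = "sirnagraph_parameter_error")
  }
  entity <- if (basis == "sirna") pairs$sirna_id else pairs$mrna_id
  entities <- unique(entity)
  if (length(entities) < 3) {
    abort(paste0("Grouped splitting by ", basis, " needs at least 3 distinct ",
                 "entities, found ", length(entities)),
          class = "sirnagraph_split_error")
  }
  n_pairs_per <- table(entity)[entities]
  set.seed(seed)
  order <- sample(length(entities))
  target <- ratio * nrow(pairs)
  counts <- c(0, 0, 0)
  assignment <- integer(length(entities))
  for (e in order) {
    deficit <- target - counts
    pick <- which.max(deficit)
    assignment[e] <- pick
    counts[pick] <- counts[pick] + n_pairs_per[[e]]
  }
  subset_of <- assignment[match(entity, entities)]
  out <- structure(
    list(train_ids = pairs$sirna_id[subset_of == 1],
         val_ids = pairs$sirna_id[subset_of == 2],
         test_ids = pairs$sirna_id[subset_of == 3],
         basis = basis, seed = seed, ratio = ratio),
    class = "split_result"
  )
  ent_sets <- lapply(1:3, function(k) unique(entity[subset_of == k]))
  stopifnot(length(intersect(ent_sets[[1]], ent_sets[[2]])) == 0,
            length(intersect(ent_sets[[1]], ent_sets[[3]])) == 0,
            length(intersect(ent_sets[[2]], ent_sets[[3]])) == 0)
  out
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> basis=", x$basis, " seed=", x$seed, " | train ",
      length(x$train_ids), " / val ", length(x$val_ids), " / test ",
      length(x$test_ids), " pairs\n", sep = "")
  invisible(x)
}

#' Pair-to-subset assignment of a split
#'
#' @param x A `split_result`.
#' @param ... Unused.
#' @return Tibble: `pair_id, subset`.
#' @method tidy split_result
#' @export
tidy.split_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble(pair_id = x$train_ids, subset = "train"),
    tibble(pair_id = x$val_ids, subset = "validation"),
    tibble(pair_id = x$test_ids, subset = "test")
  )
}

#' The full splitting protocol: both bases, many seeds
#'
#' Repeats [grouped_split()] under `n_seeds` seeds for each basis (siRNA
#' and mRNA), yielding `2 * n_seeds` distinct leakage-free splits (20 under
#' the defaults).
#'
#' @param pairs Pair tibble or [sirna_dataset()].
#' @param n_seeds Number of seeds per basis (default 10).
#' @param ratio Subset proportions.
#' @param seeds Optional explicit seed vector of length `n_seeds`.
#' @return List of `split_result` objects, length `2 * n_seeds`.
#' @export
make_all_splits <- function(pairs, n_seeds = 10L, ratio = c(0.70, 0.15, 0.15),
                            seeds = seq_len(n_seeds)) {
  stopifnot(length(seeds) == n_seeds)
  out <- list()
  for (basis in c("sirna", "mrna")) {
    for (s in seeds) {
      out[[length(out) + 1L]] <- grouped_split(pairs, basis, ratio, seed = s)
    }
  }
  out
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation,
#' `sum(((X - mean(X)) / sd(X)) * ((Y - mean(Y)) / sd(Y))) / (n - 1)`.
#'
#' @param x,y Numeric vectors of common length >= 2, each with nonzero
#'   variance.
#' @return Scalar in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2) {
    abort("pcc needs two vectors of common length >= 2",
          class = "sirnagraph_metric_error")
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    abort("pcc is undefined for a zero-variance vector",
          class = "sirnagraph_metric_error")
  }
  sum((x - mean(x)) / sx * ((y - mean(y)) / sy)) / (n - 1)
}

#' Spearman rank correlation coefficient
#'
#' Tie-free vectors use the rank-difference form
#' `1 - 6 * sum(d^2) / (n * (n^2 - 1))`; with ties the Pearson correlation
#' of average ranks is used instead.
#'
#' @inheritParams pcc
#' @return Scalar in `[-1, 1]`.
#' @export
spcc <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2) {
    abort("spcc needs two vectors of common length >= 2",
          class = "sirnagraph_metric_error")
  }
  rx <- rank(x); ry <- rank(y)
  if (anyDuplicated(x) || anyDuplicated(y)) {
    return(pcc(rx, ry))
  }
  d <- rx - ry
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Rank-based AUC of predictions against thresholded labels
#'
#' Labels are binarized at `threshold` (positive when
#' `label >= threshold`); the AUC is the Mann-Whitney statistic
#' `U / (n1 * n0)` of the predictions, with average ranks for ties.
#'
#' @param predictions Numeric predictions.
#' @param labels Numeric efficacy labels in `[0, 1]`.
#' @param threshold Efficacy cut for the positive class (default 0.7).
#' @return Scalar in `[0, 1]`.
#' @export
auc_score <- function(predictions, labels, threshold = 0.7) {
  pos <- labels >= threshold
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined when only one class is present",
          class = "sirnagraph_metric_error")
  }
  r <- rank(predictions)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predictions with the standard metric panel
#'
#' @param data Tibble holding predictions and labels.
#' @param truth,estimate Column names (default `efficacy`, `.pred`).
#' @param auc_threshold Efficacy cut for AUC binarization.
#' @return One-row tibble: `pcc, spcc, mse, auc, n`.
#' @export
evaluate_predictions <- function(data, truth = "efficacy", estimate = ".pred",
                                 auc_threshold = 0.7) {
  y <- data[[truth]]
  p <- data[[estimate]]
  auc <- tryCatch(auc_score(p, y, auc_threshold), error = function(e) NA_real_)
  tibble(
    pcc = pcc(p, y), spcc = spcc(p, y), mse = mean((p - y)^2),
    auc = auc, n = length(y)
  )
}

#' Proportion of effective siRNAs among the top-k predictions
#'
#' Ranks pairs by predicted efficacy (descending; prediction ties broken by
#' stable input order) and reports the percentage of the `k` highest-ranked
#' whose measured efficacy reaches `efficacy_cut`.
#'
#' @param predictions,labels Numeric vectors of equal length.
#' @param k Number of top predictions to inspect, `1 <= k <= n`.
#' @param efficacy_cut Efficacy threshold (default 0.7).
#' @return Percentage in `[0, 100]`.
#' @export
top_k_proportion <- function(predictions, labels, k, efficacy_cut = 0.7) {
  n <- length(predictions)
  if (k <= 0 || k > n) {
    abort("k must satisfy 1 <= k <= length(predictions)",
          class = "sirnagraph_parameter_error")
  }
  ord <- order(-predictions) # stable: ties keep input order
  100 * mean(labels[ord[seq_len(k)]] >= efficacy_cut)
}
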