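#' Declare a numeric hyperparameter
#'
#' @param name Parameter name.
#' @param lower,upper Bounds.
#' @param integer Round proposals to integers.
#' @param log Sample on a log scale.
#' @return A `tune_param` spec.
#' @export
param_numeric <- function(name, lower, upper, integer = FALSE, log = FALSE) {
  structure(list(name = name, type = "numeric", lower = lower, upper = upper,
                 integer = integer, log = log), class = "tune_param")
}

#' Declare a categorical hyperparameter
#'
#' @param name Parameter name.
#' @param values List of admissible values.
#' @return A `tune_param` spec.
#' @export
param_choice <- function(name, values) {
  structure(list(name = name, type = "choice", values = values),
            class = "tune_param")
}

sample_uniform <- function(p) {
  if (p$type == "choice") {
    return(p$values[[sample.int(length(p$values), 1)]])
  }
  x <- if (p$log) {
    exp(stats::runif(1, log(p$lower), log(p$upper)))
  } else {
    stats::runif(1, p$lower, p$upper)
  }
  if (p$integer) as.integer(round(x)) else x
}

# TPE-style proposal: model the top-quantile ("good") trials and the rest
# ("bad") with kernel densities / smoothed category counts and pick, from a
# batch of candidates drawn around the good trials, the one with the best
# good/bad density ratio.
propose_tpe <- function(p, values, scores, gamma = 0.25, n_candidates = 24L) {
  ord <- order(scores, decreasing = TRUE)
  n_good <- max(2L, ceiling(gamma * length(scores)))
  good <- values[ord[seq_len(n_good)]]
  bad <- values[ord[-seq_len(n_good)]]
  if (p$type == "choice") {
    key <- vapply(p$values, function(v) paste(deparse(v), collapse = ""), character(1))
    count_in <- function(set) {
      k <- vapply(set, function(v) paste(deparse(v), collapse = ""), character(1))
      vapply(key, function(kk) sum(k == kk), numeric(1)) + 1 # Laplace smoothing
    }
    ratio <- count_in(good) / count_in(bad)
    return(p$values[[sample.int(length(p$values), 1, prob = ratio)]])
  }
  tr <- if (p$log) log else identity
  inv <- if (p$log) exp else identity
  g <- tr(unlist(good)); b <- tr(unlist(bad))
  bw <- max(stats::sd(g), (tr(p$upper) - tr(p$lower)) / 20)
  cand <- stats::rnorm(n_candidates, mean = sample(g, n_candidates, replace = TRUE),
                       sd = bw)
  cand <- pmin(pmax(cand, tr(p$lower)), tr(p$upper))
  dens <- function(x, centers) {
    rowMeans(outer(x, centers, function(a, c) stats::dnorm(a, c, bw))) + 1e-12
  }
  ratio <- dens(cand, g) / dens(cand, if (length(b) > 0) b else g)
  x <- inv(cand[which.max(ratio)])
  if (p$integer) as.integer(round(x)) else x
}

#' Hyperparameter search maximizing a scalar objective
#'
#' Runs `n_trials` evaluations of `objective` over the search space. The
#' `"tpe"` backend (default) is a Bayesian-style sampler: after a random
#' warm-up it proposes from a kernel-density model of the best-scoring
#' trials; `"random"` is pure random search. Failed trials are logged with
#' score `NA` and skipped, not fatal.
#'
#' @param objective `function(params) -> numeric` score to maximize (e.g.
#'   validation PCC).
#' @param search_space List of [param_numeric()] / [param_choice()] specs.
#' @param n_trials Number of trials (default 100).
#' @param backend `"tpe"` or `"random"`.
#' @param seed RNG seed.
#' @param n_startup Random trials before the TPE model engages.
#' @return List with `best_params`, `best_score`, and `trials` (a tibble
#'   log with one row per trial).
#' @export
tune_model <- function(objective, search_space, n_trials = 100L,
                       backend = c("tpe", "random"), seed = 1L,
                       n_startup = 10L) {
  backend <- match.arg(backend)
  set.seed(seed)
  names(search_space) <- vapply(search_space, `[[`, character(1), "name")
  trials <- list()
  scores <- numeric(0)
  configs <- list()
  for (t in seq_len(n_trials)) {
    ok <- !is.na(scores)
    params <- lapply(search_space, function(p) {
      if (backend == "random" || sum(ok) < n_startup) {
        sample_uniform(p)
      } else {
        vals <- lapply(configs[ok], `[[`, p$name)
        propose_tpe(p, vals, scores[ok])
      }
    })
    score <- tryCatch(as.numeric(objective(params)),
                      error = function(e) {
                        warn(paste0("Trial ", t, " failed: ", conditionMessage(e)))
                        NA_real_
                      })
    configs[[t]] <- params
    scores[t] <- score
    trials[[t]] <- tibble(trial = t, score = score,
                          params = list(params))
  }
  if (all(is.na(scores))) {
    abort("All tuning trials failed", class = "sirnagraph_tune_error")
  }
  best <- which.max(scores)
  list(best_params = configs[[best]], best_score = scores[best],
       trials = dplyr::bind_rows(trials))
}

#' Objective closure: validation PCC of the GNN under a hyperparameter set
#'
#' Builds a `function(params)` suitable for [tune_model()]: each call
#' re-featurizes (if a featurization parameter changed), trains on the
#' split's training pairs and scores validation PCC. Recognized parameter
#' names: `layer1, layer2, neighbor1, neighbor2, dropout, batch_size,
#' learning_rate, epochs, positional_embedding_dim, svd_rank_mrna,
#' svd_rank_sirna, svd_rank_pair`.
#'
#' @param dataset A [sirna_dataset()].
#' @param split A [grouped_split()] result.
#' @param base_features Base [feature_config()].
#' @param base_model Base [model_config()].
#' @return A closure mapping a named parameter list to validation PCC.
#' @export
gnn_objective <- function(dataset, split, base_features = feature_config(),
                          base_model = model_config()) {
  cache <- new.env(parent = emptyenv())
  function(params) {
    fc <- base_features
    fc$positional_embedding_dim <-
      as.integer(params$positional_embedding_dim %||% fc$positional_embedding_dim)
    fc$svd_ranks$mrna <- as.integer(params$svd_rank_mrna %||% fc$svd_ranks$mrna)
    fc$svd_ranks$sirna <- as.integer(params$svd_rank_sirna %||% fc$svd_ranks$sirna)
    fc$svd_ranks$pair <- as.integer(params$svd_rank_pair %||% fc$svd_ranks$pair)
    key <- paste(fc$positional_embedding_dim, fc$svd_ranks$mrna,
                 fc$svd_ranks$sirna, fc$svd_ranks$pair, sep = "_")
    if (is.null(cache[[key]])) cache[[key]] <- build_graph(dataset, fc)
    graph <- cache[[key]]
    mc <- base_model
    mc$layer_sizes <- as.integer(c(params$layer1 %||% mc$layer_sizes[1],
                                   params$layer2 %||% mc$layer_sizes[2]))
    mc$neighbor_samples <- as.integer(c(params$neighbor1 %||% mc$neighbor_samples[1],
                                        params$neighbor2 %||% mc$neighbor_samples[2]))
    mc$dropout <- params$dropout %||% mc$dropout
    mc$batch_size <- as.integer(params$batch_size %||% mc$batch_size)
    mc$learning_rate <- params$learning_rate %||% mc$learning_rate
    mc$epochs <- as.integer(params$epochs %||% mc$epochs)
    fit <- train_sirna_sage(graph, split$train_ids, split$val_ids, mc)
    preds <- predict(fit, graph, split$val_ids)
    y <- graph$labels[match(split$val_ids, graph$pair_ids)]
    pcc(preds$.pred, y)
  }
}
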