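#' Model configuration for the heterogeneous GraphSAGE regressor
#'
#' Defaults are the tuned configuration: two layers of sizes `[64, 32]`,
#' hop neighbor samples `[12, 6]`, dropout 0.1, batch size 64, learning
#' rate 1e-3, 26 epochs, MSE loss, mean aggregator, ReLU hidden
#' activations with a linear scalar head on the interaction-node
#' representation.
#'
#' @param layer_sizes Two hidden sizes.
#' @param neighbor_samples Neighbors sampled (with replacement) per hop.
#' @param dropout Dropout rate in `[0, 1)` on hidden activations.
#' @param batch_size Minibatch size over interaction nodes.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param aggregator Neighborhood aggregator (`"mean"`).
#' @param activation Hidden nonlinearity (`"relu"`).
#' @param seed RNG seed controlling initialization, batching, sampling and
#'   dropout.
#' @return A `model_config` object.
#' @export
model_config <- function(layer_sizes = c(64L, 32L),
                         neighbor_samples = c(12L, 6L),
                         dropout = 0.1,
                         batch_size = 64L,
                         learning_rate = 1e-3,
                         epochs = 26L,
                         aggregator = "mean",
                         activation = "relu",
                         seed = 1L) {
  if (length(layer_sizes) != 2L || length(neighbor_samples) != 2L) {
    abort("layer_sizes and neighbor_samples must both have length 2",
          class = "sirnagraph_parameter_error")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("dropout must lie in [0, 1)", class = "sirnagraph_parameter_error")
  }
  aggregator <- match.arg(aggregator, "mean")
  activation <- match.arg(activation, "relu")
  structure(
    list(layer_sizes = as.integer(layer_sizes),
         neighbor_samples = as.integer(neighbor_samples),
         dropout = dropout, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         aggregator = aggregator, activation = activation,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

relu <- function(x) (x > 0) * x

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_params <- function(d_m, d_s, d_i, k1, k2) {
  list(
    W1_int = glorot(d_i + d_s + d_m, k1), b1_int = numeric(k1),
    W1_sir = glorot(d_s + d_i, k1),       b1_sir = numeric(k1),
    W1_mr  = glorot(d_m + d_i, k1),       b1_mr = numeric(k1),
    W2_int = glorot(3L * k1, k2),         b2_int = numeric(k2),
    w_out  = glorot(k2, 1L),              b_out = 0
  )
}

# Mean-aggregation weights from interaction nodes to their mRNA node.
# n_sample = NULL gives the exact full-neighborhood mean; otherwise
# neighbors are sampled with replacement (GraphSAGE semantics on
# low-degree nodes) and the empirical mean is used.
mrna_aggregation <- function(edges, n_mrna, n_int, n_sample = NULL) {
  if (is.null(n_sample)) {
    deg <- tabulate(edges$mrna, nbins = n_mrna)
    w <- 1 / deg[edges$mrna]
    ij <- cbind(edges$mrna, edges$interaction)
  } else {
    by_mrna <- split(edges$interaction, factor(edges$mrna, levels = seq_len(n_mrna)))
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (m in seq_len(n_mrna)) {
      nb <- by_mrna[[m]]
      if (length(nb) == 0) next
      samp <- nb[sample.int(length(nb), n_sample, replace = TRUE)]
      tab <- table(samp)
      rows <- c(rows, rep.int(m, length(tab)))
      cols <- c(cols, as.integer(names(tab)))
      vals <- c(vals, as.numeric(tab) / n_sample)
    }
    ij <- cbind(rows, cols)
    w <- vals
  }
  A <- matrix(0, n_mrna, n_int)
  A[ij] <- w
  A
}

# One full forward pass. Sampling enters only through A_mrna; interaction
# and siRNA nodes have single-neighbor relations whose sampled mean is the
# neighbor itself. masks = NULL disables dropout.
sage_forward <- function(params, Xm, Xs, Xi, edges, A_mrna, masks = NULL) {
  em <- edges$mrna
  C1_int <- cbind(Xi, Xs, Xm[em, , drop = FALSE])
  H1_int <- relu(C1_int %*% params$W1_int +
                   rep(params$b1_int, each = nrow(C1_int)))
  C1_sir <- cbind(Xs, Xi)
  H1_sir <- relu(C1_sir %*% params$W1_sir +
                   rep(params$b1_sir, each = nrow(C1_sir)))
  C1_mr <- cbind(Xm, A_mrna %*% Xi)
  H1_mr <- relu(C1_mr %*% params$W1_mr + rep(params$b1_mr, each = nrow(C1_mr)))
  if (!is.null(masks)) {
    H1_int <- H1_int * masks$m1_int
    H1_sir <- H1_sir * masks$m1_sir
    H1_mr <- H1_mr * masks$m1_mr
  }
  C2_int <- cbind(H1_int, H1_sir, H1_mr[em, , drop = FALSE])
  H2_int <- relu(C2_int %*% params$W2_int +
                   rep(params$b2_int, each = nrow(C2_int)))
  if (!is.null(masks)) H2_int <- H2_int * masks$m2_int
  yhat <- drop(H2_int %*% params$w_out) + params$b_out
  list(yhat = yhat, C1_int = C1_int, H1_int = H1_int, C1_sir = C1_sir,
       H1_sir = H1_sir, C1_mr = C1_mr, H1_mr = H1_mr, C2_int = C2_int,
       H2_int = H2_int)
}

sage_backward <- function(params, fw, dyhat, edges, n_mrna, masks, k1) {
  em <- edges$mrna
  g <- matrix(dyhat, ncol = 1)
  grads <- list()
  grads$w_out <- t(fw$H2_int) %*% g
  grads$b_out <- sum(g)
  dH2 <- g %*% t(params$w_out)
  dZ2 <- dH2 * (fw$H2_int > 0)
  if (!is.null(masks)) dZ2 <- dZ2 * masks$m2_int
  grads$W2_int <- t(fw$C2_int) %*% dZ2
  grads$b2_int <- colSums(dZ2)
  dC2 <- dZ2 %*% t(params$W2_int)
  dH1_int <- dC2[, seq_len(k1), drop = FALSE]
  dH1_sir <- dC2[, k1 + seq_len(k1), drop = FALSE]
  dH1_mr_rows <- dC2[, 2L * k1 + seq_len(k1), drop = FALSE]
  dH1_mr <- rowsum(dH1_mr_rows, group = factor(em, levels = seq_len(n_mrna)),
                   reorder = TRUE)
  back1 <- function(dH, H, C, mask) {
    dZ <- dH * (H > 0)
    if (!is.null(mask)) dZ <- dZ * mask
    list(W = t(C) %*% dZ, b = colSums(dZ))
  }
  bi <- back1(dH1_int, fw$H1_int, fw$C1_int, masks$m1_int)
  bs <- back1(dH1_sir, fw$H1_sir, fw$C1_sir, masks$m1_sir)
  bm <- back1(dH1_mr, fw$H1_mr, fw$C1_mr, masks$m1_mr)
  grads$W1_int <- bi$W; grads$b1_int <- bi$b
  grads$W1_sir <- bs$W; grads$b1_sir <- bs$b
  grads$W1_mr <- bm$W; grads$b1_mr <- bm$b
  grads
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

dropout_masks <- function(p, dims) {
  if (p <= 0) return(NULL)
  make <- function(n, k) {
    matrix(stats::rbinom(n * k, 1L, 1 - p), n, k) / (1 - p)
  }
  list(m1_int = make(dims$n_i, dims$k1), m1_sir = make(dims$n_i, dims$k1),
       m1_mr = make(dims$n_m, dims$k1), m2_int = make(dims$n_i, dims$k2))
}

#' Train the heterogeneous GraphSAGE efficacy regressor
#'
#' Minimizes MSE on the training interaction nodes with Adam, minibatching
#' interaction nodes and resampling mRNA neighborhoods every step. After
#' each epoch the model is evaluated on the validation set with full
#' neighborhoods and no dropout; the epoch with the best validation Pearson
#' correlation is kept. Feature scalers (z-score per dimension) are fitted
#' on training-incident nodes only and stored in the model.
#'
#' @param graph A [build_graph()] result.
#' @param train_ids,val_ids Disjoint pair-id sets (interaction nodes).
#' @param config A [model_config()].
#' @return A `sirna_sage` model object.
#' @export
train_sirna_sage <- function(graph, train_ids, val_ids,
                             config = model_config()) {
  train_idx <- match(train_ids, graph$pair_ids)
  val_idx <- match(val_ids, graph$pair_ids)
  if (anyNA(train_idx) || anyNA(val_idx)) {
    abort("Unknown pair ids in train/val sets", class = "sirnagraph_lookup_error")
  }
  if (length(train_idx) == 0) {
    abort("Empty training set", class = "sirnagraph_data_error")
  }
  if (length(intersect(train_idx, val_idx)) > 0) {
    abort("Train and validation sets overlap", class = "sirnagraph_data_error")
  }
  y <- graph$labels
  if (anyNA(y[train_idx])) {
    abort("Training pairs must carry efficacy labels",
          class = "sirnagraph_data_error")
  }

  set.seed(config$seed)
  scalers <- fit_graph_scalers(graph, train_idx)
  # the regression target is z-scored on the training labels (undone at
  # predict time) so the linear head starts on the right scale
  y_center <- mean(y[train_idx])
  y_scale <- stats::sd(y[train_idx])
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  scalers$label <- list(center = y_center, scale = y_scale)
  y <- (y - y_center) / y_scale
  Xm <- apply_scaler(graph$features$mrna, scalers$mrna)
  Xs <- apply_scaler(graph$features$sirna, scalers$sirna)
  Xi <- apply_scaler(graph$features$interaction, scalers$interaction)
  edges <- graph$edges
  n_m <- nrow(Xm); n_i <- nrow(Xi)
  k1 <- config$layer_sizes[1]; k2 <- config$layer_sizes[2]

  params <- init_params(ncol(Xm), ncol(Xs), ncol(Xi), k1, k2)
  adam <- list(t = 0L,
               m = lapply(params, function(p) p * 0),
               v = lapply(params, function(p) p * 0))
  A_full <- mrna_aggregation(edges, n_m, n_i, NULL)
  dims <- list(n_i = n_i, n_m = n_m, k1 = k1, k2 = k2)

  history <- vector("list", config$epochs)
  best <- list(pcc = -Inf, params = params, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    order <- sample(train_idx)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    for (b in batches) {
      A_s <- mrna_aggregation(edges, n_m, n_i, config$neighbor_samples[2])
      masks <- dropout_masks(config$dropout, dims)
      fw <- sage_forward(params, Xm, Xs, Xi, edges, A_s, masks)
      dyhat <- numeric(n_i)
      dyhat[b] <- 2 * (fw$yhat[b] - y[b]) / length(b)
      grads <- sage_backward(params, fw, dyhat, edges, n_m, masks, k1)
      upd <- adam_step(adam, params, grads, config$learning_rate)
      adam <- upd$state
      params <- upd$params
    }
    fw <- sage_forward(params, Xm, Xs, Xi, edges, A_full, NULL)
    pred <- fw$yhat * y_scale + y_center # original label scale
    y_orig <- graph$labels
    train_mse <- mean((pred[train_idx] - y_orig[train_idx])^2)
    val_mse <- val_pcc <- NA_real_
    if (length(val_idx) >= 2 && !anyNA(y_orig[val_idx])) {
      val_mse <- mean((pred[val_idx] - y_orig[val_idx])^2)
      if (stats::sd(pred[val_idx]) > 0 && stats::sd(y_orig[val_idx]) > 0) {
        val_pcc <- pcc(pred[val_idx], y_orig[val_idx])
      }
    }
    history[[epoch]] <- tibble(epoch = epoch, train_mse = train_mse,
                               val_mse = val_mse, val_pcc = val_pcc)
    score <- if (is.na(val_pcc)) -val_mse else val_pcc
    if (is.na(score)) score <- -train_mse
    if (score > best$pcc) {
      best <- list(pcc = score, params = params, epoch = epoch)
    }
  }

  structure(
    list(params = best$params, final_params = params, scalers = scalers,
         config = config, history = dplyr::bind_rows(history),
         best_epoch = best$epoch,
         input_dims = c(mrna = ncol(Xm), sirna = ncol(Xs),
                        interaction = ncol(Xi))),
    class = "sirna_sage"
  )
}

#' @export
print.sirna_sage <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<sirna_sage> two-layer heterogeneous GraphSAGE regressor\n")
  cat("  hidden sizes: ", paste(x$config$layer_sizes, collapse = ", "),
      "; parameters: ", np, "\n", sep = "")
  cat("  best epoch: ", x$best_epoch, " of ", x$config$epochs, "\n", sep = "")
  invisible(x)
}

#' Predict silencing efficacy for interaction nodes
#'
#' Inference uses full neighborhoods (no sampling) and no dropout, so
#' predictions are deterministic.
#'
#' @param object A trained `sirna_sage` model.
#' @param graph The [build_graph()] graph to predict on (must have the same
#'   feature dimensions the model was trained with).
#' @param ids Pair ids to predict; default all interaction nodes.
#' @param ... Unused.
#' @return Tibble with columns `pair_id`, `.pred`.
#' @export
predict.sirna_sage <- function(object, graph, ids = NULL, ...) {
  dims <- vapply(graph$features, ncol, integer(1))
  if (!identical(unname(dims[c("mrna", "sirna", "interaction")]),
                 unname(object$input_dims[c("mrna", "sirna", "interaction")]))) {
    abort("Graph feature dimensions do not match the trained model",
          class = "sirnagraph_shape_error")
  }
  ids <- ids %||% graph$pair_ids
  idx <- match(ids, graph$pair_ids)
  if (anyNA(idx)) {
    abort(paste0("Unknown pair id(s): ",
                 paste(utils::head(ids[is.na(idx)], 5), collapse = ", ")),
          class = "sirnagraph_lookup_error")
  }
  Xm <- apply_scaler(graph$features$mrna, object$scalers$mrna)
  Xs <- apply_scaler(graph$features$sirna, object$scalers$sirna)
  Xi <- apply_scaler(graph$features$interaction, object$scalers$interaction)
  A_full <- mrna_aggregation(graph$edges, nrow(Xm), nrow(Xi), NULL)
  fw <- sage_forward(object$params, Xm, Xs, Xi, graph$edges, A_full, NULL)
  lab <- object$scalers$label %||% list(center = 0, scale = 1)
  tibble(pair_id = ids, .pred = fw$yhat[idx] * lab$scale + lab$center)
}
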