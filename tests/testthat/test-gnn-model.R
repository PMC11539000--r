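make_small_graph <- function(seed = 31L) {
  set.seed(seed)
  m1 <- random_rna(100)
  m2 <- random_rna(90)
  mk <- function(i, m_id, m_seq, st) {
    tibble::tibble(sirna_id = paste0("s", i),
                   sequence = rna_revcomp(substr(m_seq, st + 1, st + 19)),
                   mrna_id = m_id, target_start = st,
                   efficacy = stats::runif(1))
  }
  pairs <- dplyr::bind_rows(mk(1, "m1", m1, 5), mk(2, "m1", m1, 40),
                            mk(3, "m2", m2, 11))
  ds <- sirna_dataset(pairs, tibble::tibble(id = c("m1", "m2"),
                                            sequence = c(m1, m2)))
  build_graph(ds, fast_feature_config())
}

test_that("model configuration enforces the two-layer contract", {
  expect_error(model_config(layer_sizes = c(64, 32, 16)),
               class = "sirnagraph_parameter_error")
  expect_error(model_config(dropout = 1), class = "sirnagraph_parameter_error")
  mc <- model_config()
  expect_equal(mc$layer_sizes, c(64L, 32L))
  expect_equal(mc$neighbor_samples, c(12L, 6L))
})

test_that("vectorized forward pass equals the dense per-node oracle", {
  g <- make_small_graph() # 2 + 3 + 3 = 8 nodes
  set.seed(32)
  Xm <- matrix(rnorm(2 * 5), 2)
  Xs <- matrix(rnorm(3 * 4), 3)
  Xi <- matrix(rnorm(3 * 3), 3)
  params <- sirnagraph:::init_params(5, 4, 3, 6, 4)
  A_full <- sirnagraph:::mrna_aggregation(g$edges, 2, 3, NULL)
  fw <- sirnagraph:::sage_forward(params, Xm, Xs, Xi, g$edges, A_full, NULL)
  oracle <- bf_sage_forward(params, Xm, Xs, Xi, g$edges)
  expect_equal(fw$yhat, oracle, tolerance = 1e-6)
})

test_that("mean aggregation over a sampled multiset of one neighbor is that neighbor", {
  edges <- tibble::tibble(interaction = 1L, sirna = 1L, mrna = 1L)
  set.seed(33)
  A <- sirnagraph:::mrna_aggregation(edges, 1, 1, n_sample = 12)
  expect_equal(as.numeric(A), 1) # duplicated neighbor averages to itself
  # full aggregation over several neighbors is the exact mean
  edges3 <- tibble::tibble(interaction = 1:3, sirna = 1:3, mrna = c(1L, 1L, 1L))
  A3 <- sirnagraph:::mrna_aggregation(edges3, 1, 3, NULL)
  expect_equal(as.numeric(A3), rep(1 / 3, 3))
})

test_that("training is seeded-deterministic and sensitive to the seed", {
  g <- make_small_graph()
  ids <- g$pair_ids
  mc <- model_config(epochs = 3L, batch_size = 2L, seed = 7L)
  f1 <- train_sirna_sage(g, ids[1:2], ids[3], mc)
  f2 <- train_sirna_sage(g, ids[1:2], ids[3], mc)
  expect_equal(f1$history, f2$history)
  expect_equal(predict(f1, g)$.pred, predict(f2, g)$.pred)
  f3 <- train_sirna_sage(g, ids[1:2], ids[3], model_config(epochs = 3L,
                                                           batch_size = 2L,
                                                           seed = 8L))
  expect_false(isTRUE(all.equal(f1$params$w_out, f3$params$w_out)))
})

test_that("training loss decreases on a noiseless monotone dataset", {
  ds <- simulate_dataset(fast_sim_config(
    seed = 34, noise_sd = 0,
    effect_weights = c(gc = -1, thermo_end_differential = 0, position = 0,
                       motif = 0)))
  g <- build_graph(ds, fast_feature_config())
  sp <- grouped_split(ds, "sirna", seed = 2)
  fit <- train_sirna_sage(g, sp$train_ids, sp$val_ids,
                          model_config(epochs = 10L, seed = 1L))
  h <- tidy(fit)
  expect_lt(h$train_mse[nrow(h)], h$train_mse[1])
})

test_that("prediction is aligned, finite and guarded", {
  g <- make_small_graph()
  ids <- g$pair_ids
  mc <- model_config(epochs = 2L, batch_size = 2L, seed = 1L)
  fit <- train_sirna_sage(g, ids[1:2], ids[3], mc)
  p_fwd <- predict(fit, g, ids)
  p_rev <- predict(fit, g, rev(ids))
  expect_equal(p_rev$.pred, rev(p_fwd$.pred))
  expect_true(all(is.finite(p_fwd$.pred)))
  expect_error(predict(fit, g, "ghost"), class = "sirnagraph_lookup_error")
  expect_error(train_sirna_sage(g, character(0), ids[3], mc),
               class = "sirnagraph_data_error")
  expect_error(train_sirna_sage(g, ids[1:2], ids[2], mc),
               class = "sirnagraph_data_error")
})

test_that("predictions are equivariant under pair relabeling", {
  set.seed(35)
  ds <- simulate_dataset(fast_sim_config(seed = 36))
  g <- build_graph(ds, fast_feature_config())
  sp <- grouped_split(ds, "sirna", seed = 1)
  fit <- train_sirna_sage(g, sp$train_ids, sp$val_ids,
                          model_config(epochs = 2L, seed = 1L))
  perm <- sample(nrow(ds$pairs))
  ds_perm <- sirna_dataset(ds$pairs[perm, ], ds$mrnas)
  g_perm <- build_graph(ds_perm, fast_feature_config())
  ids <- g$pair_ids
  expect_equal(predict(fit, g_perm, ids)$.pred, predict(fit, g, ids)$.pred,
               tolerance = 1e-10)
})

test_that("model checkpoints round-trip through JSON", {
  g <- make_small_graph()
  ids <- g$pair_ids
  fit <- train_sirna_sage(g, ids[1:2], ids[3],
                          model_config(epochs = 2L, batch_size = 2L, seed = 1L))
  path <- withr::local_tempfile(fileext = ".json")
  save_sirna_sage(fit, path)
  back <- load_sirna_sage(path)
  expect_equal(predict(back, g)$.pred, predict(fit, g)$.pred, tolerance = 1e-12)
  expect_equal(back$best_epoch, fit$best_epoch)
})
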