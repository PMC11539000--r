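one_mrna_pairs <- function(n = 100L) {
  tibble::tibble(sirna_id = sprintf("s%03d", seq_len(n)),
                 sequence = replicate(n, random_rna(19)),
                 mrna_id = "m1", target_start = 0L,
                 efficacy = stats::runif(n))
}

test_that("grouped splitting hits the 70/15/15 ratio on equal-sized entities", {
  set.seed(41)
  pairs <- one_mrna_pairs(100L)
  sp <- grouped_split(pairs, "sirna", seed = 3)
  expect_length(sp$train_ids, 70)
  expect_length(sp$val_ids, 15)
  expect_length(sp$test_ids, 15)
  expect_error(grouped_split(pairs, "mrna"), class = "sirnagraph_split_error")
  expect_error(grouped_split(pairs, "sirna", ratio = c(0.5, 0.2, 0.2)),
               class = "sirnagraph_parameter_error")
  # determinism
  expect_equal(grouped_split(pairs, "sirna", seed = 3)$train_ids, sp$train_ids)
})

test_that("no basis entity ever crosses subsets", {
  set.seed(42)
  ds <- simulate_dataset(fast_sim_config(seed = 43))
  for (basis in c("sirna", "mrna")) {
    if (basis == "mrna" && length(unique(ds$pairs$mrna_id)) < 3) next
    sp <- grouped_split(ds, basis, seed = 5)
    key <- if (basis == "sirna") "sirna_id" else "mrna_id"
    ent <- function(ids) unique(ds$pairs[[key]][ds$pairs$sirna_id %in% ids])
    expect_length(intersect(ent(sp$train_ids), ent(sp$test_ids)), 0)
    expect_length(intersect(ent(sp$train_ids), ent(sp$val_ids)), 0)
    expect_length(intersect(ent(sp$val_ids), ent(sp$test_ids)), 0)
    expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), ds$pairs$sirna_id)
  }
})

test_that("grouped proportions converge with many entities (property)", {
  set.seed(44)
  pairs <- one_mrna_pairs(1000L)
  sp <- grouped_split(pairs, "sirna", seed = 1)
  props <- c(length(sp$train_ids), length(sp$val_ids), length(sp$test_ids)) / 1000
  expect_true(all(abs(props - c(0.70, 0.15, 0.15)) < 0.02))
})

test_that("the full protocol yields 2 bases x n_seeds splits", {
  ds <- simulate_dataset(fast_sim_config(seed = 45))
  splits <- make_all_splits(ds$pairs, n_seeds = 2L)
  expect_length(splits, 4)
  expect_setequal(vapply(splits, `[[`, character(1), "basis"),
                  c("sirna", "mrna"))
  again <- make_all_splits(ds$pairs, n_seeds = 2L)
  expect_equal(tidy(splits[[1]]), tidy(again[[1]]))
  single <- make_all_splits(ds$pairs, n_seeds = 1L)
  expect_length(single, 2)
})

test_that("pearson correlation matches its definition and guards", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(x, y), bf_pearson(x, y), tolerance = 1e-12)
  expect_equal(pcc(x, y), 0.9819805, tolerance = 1e-6)
  expect_error(pcc(c(1, 1, 1), y), class = "sirnagraph_metric_error")
  expect_error(pcc(1, 2), class = "sirnagraph_metric_error")
})

test_that("spearman correlation uses the rank-difference form and tie fallback", {
  expect_equal(spcc(1:5, 1:5), 1)
  expect_equal(spcc(1:5, 5:1), -1)
  expect_equal(spcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8) # d = (0,1,-1,0)
  xt <- c(1, 1, 2, 3); yt <- c(2, 1, 3, 3)
  expect_equal(spcc(xt, yt), bf_spearman(xt, yt), tolerance = 1e-12)
})

test_that("correlations agree with textbook oracles on random vectors", {
  set.seed(46)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    expect_equal(pcc(x, y), bf_pearson(x, y), tolerance = 1e-10)
    expect_equal(spcc(x, y), bf_spearman(x, y), tolerance = 1e-10)
  }
})

test_that("rank AUC equals exhaustive pair counting", {
  pred <- c(0.9, 0.8, 0.4, 0.2)
  lab <- c(0.9, 0.8, 0.3, 0.1)
  expect_equal(auc_score(pred, lab), 1)
  expect_error(auc_score(pred, c(0.9, 0.9, 0.8, 0.95)),
               class = "sirnagraph_metric_error")
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    p <- stats::rnorm(n)
    l <- stats::runif(n)
    if (all(l >= 0.7) || all(l < 0.7)) next
    expect_equal(auc_score(p, l), bf_auc(p, l >= 0.7), tolerance = 1e-12)
  }
  # class-independent predictions hover near 1/2
  p <- stats::rnorm(4000); l <- stats::runif(4000)
  expect_lt(abs(auc_score(p, l) - 0.5), 0.05)
})

test_that("top-k proportion ranks by prediction with stable ties", {
  lab <- c(0.9, 0.8, 0.75, 0.72, 0.71, 0.3, 0.2, 0.6, 0.65, 0.1)
  pred <- c(10, 9, 8, 7, 6, 5.5, 5, 4, 3, 1)
  expect_equal(top_k_proportion(pred, lab, 5), 100)
  expect_equal(top_k_proportion(pred, lab, 7), 100 * 5 / 7)
  expect_equal(top_k_proportion(pred, lab, 10), 100 * mean(lab >= 0.7))
  expect_equal(top_k_proportion(rep(1, 10), lab, 3), 100) # stable input order
  expect_error(top_k_proportion(pred, lab, 0), class = "sirnagraph_parameter_error")
  all_hi <- rep(0.95, 6)
  expect_equal(top_k_proportion(stats::rnorm(6), all_hi, 4), 100)
})

test_that("the metric panel reports a consistent row", {
  set.seed(48)
  d <- tibble::tibble(efficacy = stats::runif(40),
                      .pred = stats::runif(40))
  rep <- evaluate_predictions(d)
  expect_named(rep, c("pcc", "spcc", "mse", "auc", "n"))
  expect_equal(rep$n, 40)
  expect_equal(rep$mse, mean((d$.pred - d$efficacy)^2))
})
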