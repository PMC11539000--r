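# Fixtures are built in code at test time; no files ship with the tests.

seq_chars <- function(s) strsplit(s, "")[[1]]

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A tiny handcrafted dataset: two mRNAs, four guides that are exact
# reverse complements of their target windows.
tiny_dataset <- function(n_guides = 4L, mrna_len = 80L, seed = 42L) {
  set.seed(seed)
  mrnas <- tibble::tibble(
    id = c("mA", "mB"),
    sequence = vapply(rep(mrna_len, 2), random_rna, character(1))
  )
  mrnas$length <- nchar(mrnas$sequence)
  rows <- lapply(seq_len(n_guides), function(i) {
    j <- (i %% 2) + 1L
    start <- sample(0:(mrna_len - 19L), 1)
    window <- substr(mrnas$sequence[j], start + 1L, start + 19L)
    tibble::tibble(
      sirna_id = paste0("si", i), sequence = rna_revcomp(window),
      mrna_id = mrnas$id[j], target_start = start,
      efficacy = round(stats::runif(1), 3)
    )
  })
  sirna_dataset(dplyr::bind_rows(rows), mrnas)
}

# small, fast featurization for unit tests
fast_feature_config <- function(...) {
  feature_config(svd_ranks = list(mrna = 10, sirna = 4, pair = 8),
                 cofold_window = 40L, ...)
}

fast_sim_config <- function(seed = 1L, ...) {
  simulation_config(n_mrna = 3L, sirna_per_mrna = 10L,
                    mrna_length_range = c(80L, 140L), seed = seed, ...)
}

# --- independent brute-force oracles -------------------------------------

bf_pearson <- function(x, y) stats::cor(x, y)

bf_spearman <- function(x, y) stats::cor(x, y, method = "spearman")

# AUC by exhaustive pair counting (ties count 1/2)
bf_auc <- function(pred, positive) {
  pp <- pred[positive]
  pn <- pred[!positive]
  cmp <- outer(pp, pn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# dense per-node message passing: the two-layer update rule written as
# plain loops over nodes, independent of the package's vectorized path
bf_sage_forward <- function(params, Xm, Xs, Xi, edges) {
  n_i <- nrow(Xi); n_m <- nrow(Xm)
  relu <- function(v) pmax(v, 0)
  agg_mean <- function(rows) {
    if (length(rows) == 0) return(NULL)
    colMeans(rows)
  }
  H1_int <- matrix(0, n_i, length(params$b1_int))
  H1_sir <- matrix(0, n_i, length(params$b1_sir))
  H1_mr <- matrix(0, n_m, length(params$b1_mr))
  for (v in seq_len(n_i)) {
    h <- c(Xi[v, ], c(Xs[edges$sirna[v], ], Xm[edges$mrna[v], ]))
    H1_int[v, ] <- relu(drop(h %*% params$W1_int) + params$b1_int)
    h <- c(Xs[v, ], Xi[v, ]) # the guide's single interaction neighbor
    H1_sir[v, ] <- relu(drop(h %*% params$W1_sir) + params$b1_sir)
  }
  for (m in seq_len(n_m)) {
    nb <- which(edges$mrna == m)
    agg <- if (length(nb)) colMeans(Xi[nb, , drop = FALSE]) else 0 * Xi[1, ]
    h <- c(Xm[m, ], agg)
    H1_mr[m, ] <- relu(drop(h %*% params$W1_mr) + params$b1_mr)
  }
  yhat <- numeric(n_i)
  for (v in seq_len(n_i)) {
    h <- c(H1_int[v, ], H1_sir[v, ], H1_mr[edges$mrna[v], ])
    h2 <- relu(drop(h %*% params$W2_int) + params$b2_int)
    yhat[v] <- drop(h2 %*% params$w_out) + params$b_out
  }
  yhat
}

write_dataset_files <- function(dataset, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_pairs(dataset, file.path(dir, "pairs.tsv"), file.path(dir, "mrnas.fasta"))
  dir
}
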