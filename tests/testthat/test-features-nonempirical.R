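test_that("one-hot encoding follows the A/C/G/U column convention", {
  expect_equal(one_hot_encode("A"), matrix(c(1L, 0L, 0L, 0L), 1,
                                           dimnames = list(NULL, c("A", "C", "G", "U"))))
  expect_equal(unname(one_hot_encode("N")[1, ]), c(0L, 0L, 0L, 0L))
  m <- one_hot_encode("ACGU")
  expect_equal(unname(m), diag(4L) * 1L, ignore_attr = TRUE)
  expect_error(one_hot_encode("ACXU"), class = "sirnagraph_alphabet_error")
})

test_that("one-hot row sums are 1 minus the N indicator (property)", {
  set.seed(1)
  for (rep in 1:25) {
    s <- random_rna(sample(5:40, 1), alphabet = c("A", "C", "G", "U", "N"))
    m <- one_hot_encode(s)
    expect_equal(rowSums(m), as.numeric(seq_chars(s) != "N"), ignore_attr = TRUE)
  }
})

test_that("positional embedding matches its closed form", {
  expect_equal(positional_embedding(0, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(positional_embedding(1, 2), c(sin(1), cos(1)))
  # channel j = 2 (0-based) of i = 500, D = 6: sin(500 / 10000^(2/5))
  expect_equal(positional_embedding(500, 6)[3], sin(500 / 10000^(2 / 5)))
  expect_equal(positional_embedding(500, 6)[4], cos(500 / 10000^(2 / 5)))
  expect_error(positional_embedding(3, 1), class = "sirnagraph_parameter_error")
  expect_error(positional_embedding(-1, 6), class = "sirnagraph_parameter_error")
})

test_that("positional embedding entries stay within [-1, 1] (property)", {
  set.seed(2)
  for (rep in 1:50) {
    v <- positional_embedding(sample(0:10000, 1), sample(2:16, 1))
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("null engine produces bounded, symmetric, complementarity-driven maps", {
  eng <- fold_engine("null")
  flat <- fold_pairing_matrix("AAAAAAA", eng)
  expect_true(all(flat == 0)) # nothing can pair
  stem <- fold_pairing_matrix("GGGGAAAACCCC", eng)
  expect_true(stem[1, 12] > 0 && stem[2, 11] > 0)
  expect_equal(stem, t(stem), ignore_attr = TRUE)
  set.seed(3)
  for (rep in 1:10) {
    m <- fold_pairing_matrix(random_rna(sample(10:40, 1)), eng)
    expect_true(all(m >= 0 & m <= 1))
    expect_lt(max(abs(m - t(m))), 1e-12)
  }
  expect_error(fold_pairing_matrix("AU", eng),
               class = "sirnagraph_precondition_error")
})

test_that("null co-fold puts intermolecular mass on a complementary duplex", {
  eng <- fold_engine("null")
  mrna <- "GGGAUGCUUAGCGAUCGAUA"
  guide <- rna_revcomp(mrna)
  m <- cofold_pairing_matrix(guide, mrna, eng)
  n <- nchar(guide)
  inter <- m[seq_len(n), n + seq_len(nchar(mrna))]
  expect_gt(sum(inter), 0)
  # the perfect-duplex anti-diagonal carries far more mass per entry than
  # the chance-complementarity background of the block
  anti <- diag(inter[, rev(seq_len(ncol(inter)))])
  expect_true(all(anti > 0))
  expect_gt(mean(anti), 3 * mean(inter))
  expect_error(cofold_pairing_matrix("", mrna, eng),
               class = "sirnagraph_precondition_error")
})

test_that("vienna engine parses partition-function dot plots", {
  eng <- fold_engine("vienna")
  m <- fold_pairing_matrix("GGGGAAAACCCC", eng)
  expect_equal(dim(m), c(12, 12))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m), ignore_attr = TRUE)
  # the G:C stem (1-12, 2-11, 3-10, 4-9) carries most of the mass
  stem <- m[cbind(1:4, 12:9)]
  expect_true(all(stem > 0.5))
  unpaired <- fold_pairing_matrix("AAAAAAAAAA", eng)
  expect_lt(max(unpaired), 0.05)

  guide <- "UUUGCGGCUAAGCUAGG"
  duplex <- cofold_pairing_matrix(guide, rna_revcomp(guide), eng)
  expect_equal(dim(duplex), c(34, 34))
  inter <- duplex[1:17, 18:34]
  expect_gt(max(inter), 0.5)
})

test_that("svd reduction returns padded, ordered singular values", {
  expect_equal(svd_reduce(diag(5), 3), c(1, 1, 1))
  expect_equal(svd_reduce(matrix(0, 4, 4), 4), rep(0, 4))
  set.seed(4)
  a <- matrix(rnorm(100), 10)
  sym <- (a + t(a)) / 2
  got <- svd_reduce(sym, 10)
  expect_equal(got, svd(sym)$d, tolerance = 1e-10) # independent dense SVD
  expect_true(all(diff(got) <= 1e-12))
  # rank above matrix size: zero-padded
  expect_equal(svd_reduce(diag(2), 5), c(1, 1, 0, 0, 0))
})

test_that("singular-value features are permutation-invariant and norm-conserving", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    perm <- sample(n)
    expect_equal(svd_reduce(m[perm, perm], n), svd_reduce(m, n), tolerance = 1e-9)
    expect_equal(sum(svd_reduce(m, n)^2), sum(m^2), tolerance = 1e-8)
  }
})

test_that("interaction providers are deterministic, bounded and lookup-backed", {
  stub <- interaction_provider("stub")
  s <- random_rna(21)
  p1 <- rna_protein_interaction(s, provider = stub)
  expect_identical(p1, rna_protein_interaction(s, provider = stub))
  expect_true(p1 >= 0 && p1 <= 1)

  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = c("g1", "g2"), probability = c(0.83, 0.2)), f)
  filep <- interaction_provider("file", path = f)
  expect_equal(rna_protein_interaction("ACGU", id = "g1", provider = filep), 0.83)
  expect_error(rna_protein_interaction("ACGU", id = "missing", provider = filep),
               class = "sirnagraph_lookup_error")
  expect_error(rna_protein_interaction("ACGU", provider = "bogus"),
               class = "sirnagraph_config_error")
})

test_that("out-of-range provider probabilities violate the contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = "g1", probability = 1.7), f)
  filep <- interaction_provider("file", path = f)
  expect_error(rna_protein_interaction("ACGU", id = "g1", provider = filep),
               class = "sirnagraph_contract_error")
})
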