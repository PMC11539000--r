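test_that("thermodynamic profile decomposes into nearest-neighbor steps", {
  nn <- load_nn_table()
  one <- thermo_profile("AA", nn)
  expect_equal(one$dinucleotide_dG, unname(nn[["AA"]]))
  expect_equal(one$dinucleotide_dG, -0.93) # bundled table value
  expect_equal(one$total_dG, -0.93)
  expect_equal(one$end_differential_dG, 0)

  sym <- thermo_profile("AAA", nn) # first and last step identical
  expect_equal(sym$end_differential_dG, 0)

  set.seed(11)
  for (rep in 1:10) {
    s <- random_rna(sample(19:23, 1))
    tp <- thermo_profile(s, nn)
    expect_equal(tp$total_dG, sum(tp$dinucleotide_dG), tolerance = 1e-12)
    expect_length(tp$dinucleotide_dG, nchar(s) - 1)
  }
})

test_that("profile of concatenated halves shares all non-junction steps", {
  a <- "GCAUGCAUGC"
  b <- "UUAGCCGAUA"
  full <- thermo_profile(paste0(a, b))$dinucleotide_dG
  left <- thermo_profile(a)$dinucleotide_dG
  right <- thermo_profile(b)$dinucleotide_dG
  expect_equal(full[seq_along(left)], left)
  expect_equal(full[(length(left) + 2):length(full)], right)
})

test_that("incomplete nearest-neighbor tables are rejected", {
  nn <- load_nn_table()
  expect_error(thermo_profile("ANA", nn), class = "sirnagraph_table_error")
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(dinucleotide = "AA", dG_kcal_per_mol = -0.9), f)
  expect_error(load_nn_table(f), class = "sirnagraph_table_error")
})

test_that("wider terminal windows average multiple steps", {
  nn <- load_nn_table()
  s <- "GGGCAUAUAUAUAUAGC"
  tp2 <- thermo_profile(s, nn, end_window = 2L)
  dg <- thermo_profile(s, nn)$dinucleotide_dG
  expect_equal(tp2$end_differential_dG,
               mean(dg[1:2]) - mean(dg[(length(dg) - 1):length(dg)]))
})

test_that("k-mer counting enumerates the full motif dictionary", {
  v <- kmer_frequencies("AAAAA", k_max = 1)
  expect_equal(unname(v["A"]), 5)
  expect_equal(sum(v), 5)

  v2 <- kmer_frequencies("AUAUA", k_max = 2)
  expect_equal(unname(v2[c("AU", "UA")]), c(2, 2))
  expect_equal(sum(v2[nchar(names(v2)) == 2]), 4)

  expect_error(kmer_frequencies("ACG", k_max = 5),
               class = "sirnagraph_length_error")
})

test_that("k-mer block sums match the sliding-window count (property)", {
  set.seed(12)
  for (rep in 1:10) {
    s <- random_rna(sample(19:23, 1))
    v <- kmer_frequencies(s, k_max = 5)
    L <- nchar(s)
    for (k in 1:5) {
      block <- v[nchar(names(v)) == k]
      expect_length(block, 4^k)
      expect_equal(sum(block), L - k + 1)
      # brute-force sliding window
      wins <- vapply(seq_len(L - k + 1), function(i) substr(s, i, i + k - 1),
                     character(1))
      bf <- vapply(names(block), function(mm) sum(wins == mm), numeric(1))
      expect_equal(unname(as.numeric(block)), unname(bf))
    }
  }
})

test_that("N-containing windows are skipped and normalization rescales blocks", {
  v <- kmer_frequencies("AANAA", k_max = 2)
  expect_equal(sum(v[nchar(names(v)) == 1]), 4) # the N itself is uncounted
  expect_equal(sum(v[nchar(names(v)) == 2]), 2) # AN / NA windows skipped
  vn <- kmer_frequencies("ACGUA", k_max = 2, normalize = TRUE)
  expect_equal(sum(vn[nchar(names(vn)) == 2]), 1)
})

test_that("G/C percentage counts non-N bases and ignores orientation", {
  expect_equal(gc_percentage("GCGC"), 100)
  expect_equal(gc_percentage("AUAU"), 0)
  expect_equal(gc_percentage("GCAU"), 50)
  expect_equal(gc_percentage("GCNN"), 100)
  expect_error(gc_percentage("NNN"), class = "sirnagraph_validation_error")
  set.seed(13)
  for (rep in 1:10) {
    s <- random_rna(21)
    rev_s <- paste(rev(seq_chars(s)), collapse = "")
    expect_equal(gc_percentage(s), gc_percentage(rev_s))
  }
})

test_that("rule codes expand the -1/0/+1 table to one-hot rows", {
  empty <- tibble::tibble(position = integer(), nucleotide = character(),
                          code = integer())
  m <- rule_codes(random_rna(19), empty)
  expect_equal(unname(m), matrix(rep(c(0L, 1L, 0L), each = 1), 19, 3,
                                 byrow = TRUE), ignore_attr = TRUE)

  tab <- tibble::tibble(position = c(1L, 1L), nucleotide = c("U", "G"),
                        code = c(1L, -1L))
  mu <- rule_codes(paste0("U", random_rna(18)), tab)
  expect_equal(unname(mu[1, ]), c(0L, 0L, 1L))
  mg <- rule_codes(paste0("G", random_rna(18)), tab)
  expect_equal(unname(mg[1, ]), c(1L, 0L, 0L))

  set.seed(14)
  for (rep in 1:10) {
    m <- rule_codes(random_rna(sample(19:23, 1)))
    expect_true(all(rowSums(m) == 1))
  }
})

test_that("malformed rule tables are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(position = 1, nucleotide = "U", code = 7), f)
  expect_error(load_rule_table(f), class = "sirnagraph_schema_error")
  readr::write_tsv(tibble::tibble(pos = 1, nt = "U", code = 1), f)
  expect_error(load_rule_table(f), class = "sirnagraph_schema_error")
})
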