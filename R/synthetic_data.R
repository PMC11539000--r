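#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the shape of real siRNA screens: few mRNAs, many
#' siRNAs per mRNA, continuous efficacy labels in `[0, 1]`. Guides are
#' exact reverse complements of sampled target windows, and the latent
#' efficacy is a logistic function of z-scored covariates the pipeline
#' actually extracts — G/C percentage, the thermodynamic end differential,
#' the relative site position — plus a centered homopolymer-motif
#' indicator, with Gaussian noise. Negative `gc` weight encodes the
#' lower-GC-is-better preference.
#'
#' @param n_mrna Number of mRNAs (default 5).
#' @param sirna_per_mrna Guides per mRNA (default 100).
#' @param mrna_length_range Min/max mRNA length (default 500-1500 nt).
#' @param sirna_length Guide length in 19-23 (default 21).
#' @param effect_weights Named weights for `gc`,
#'   `thermo_end_differential`, `position`, `motif`.
#' @param noise_sd Gaussian noise SD on the efficacy (default 0.05).
#' @param seed RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_mrna = 5L, sirna_per_mrna = 100L,
                              mrna_length_range = c(500L, 1500L),
                              sirna_length = 21L,
                              effect_weights = c(gc = -1.0,
                                                 thermo_end_differential = 0.7,
                                                 position = -0.3,
                                                 motif = 0.5),
                              noise_sd = 0.05, seed = 1L) {
  stopifnot(n_mrna >= 1, sirna_per_mrna >= 1,
            sirna_length >= 19, sirna_length <= 23)
  if (mrna_length_range[1] < sirna_length) {
    abort("mRNAs must be at least as long as the guides",
          class = "sirnagraph_config_error")
  }
  w <- c(gc = 0, thermo_end_differential = 0, position = 0, motif = 0)
  w[names(effect_weights)] <- effect_weights
  structure(
    list(n_mrna = as.integer(n_mrna),
         sirna_per_mrna = as.integer(sirna_per_mrna),
         mrna_length_range = as.integer(mrna_length_range),
         sirna_length = as.integer(sirna_length),
         effect_weights = w, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a synthetic siRNA-mRNA dataset
#'
#' Draws random mRNAs, samples non-duplicated target windows, takes guides
#' as exact reverse complements (so every pair passes [validate_site()]
#' without a mismatch warning), and assigns efficacies from the latent
#' model described in [simulation_config()]. When `dir` is given the exact
#' on-disk formats the loaders read are written (`pairs.tsv`,
#' `mrnas.fasta`) together with a `truth.json` sidecar of ground-truth
#' weights and latent covariates.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory.
#' @return A [sirna_dataset()] with attribute `truth` (list: the weights
#'   and the per-pair latent covariates).
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  set.seed(config$seed)
  L <- config$sirna_length
  nn <- load_nn_table()

  mrnas <- tibble(
    id = sprintf("mrna_%02d", seq_len(config$n_mrna)),
    sequence = vapply(seq_len(config$n_mrna), function(j) {
      len <- sample(seq(config$mrna_length_range[1], config$mrna_length_range[2]), 1)
      paste(sample(RNA_BASES, len, replace = TRUE), collapse = "")
    }, character(1))
  )
  mrnas$length <- nchar(mrnas$sequence)

  rows <- list()
  for (j in seq_len(config$n_mrna)) {
    mlen <- mrnas$length[j]
    starts <- sample(0:(mlen - L), config$sirna_per_mrna,
                     replace = config$sirna_per_mrna > mlen - L + 1)
    for (s in seq_along(starts)) {
      window <- substr(mrnas$sequence[j], starts[s] + 1L, starts[s] + L)
      rows[[length(rows) + 1L]] <- tibble(
        sirna_id = sprintf("si_%02d_%03d", j, s),
        sequence = rna_revcomp(window),
        mrna_id = mrnas$id[j],
        target_start = starts[s],
        relative_position = starts[s] / mlen
      )
    }
  }
  pairs <- dplyr::bind_rows(rows)

  gc <- vapply(pairs$sequence, gc_percentage, numeric(1))
  ed <- vapply(pairs$sequence, function(s) {
    thermo_profile(s, nn)$end_differential_dG
  }, numeric(1))
  motif <- as.numeric(grepl("AAAA|UUUU|CCCC|GGGG", pairs$sequence))
  w <- config$effect_weights
  latent <- w[["gc"]] * zscore(gc) +
    w[["thermo_end_differential"]] * zscore(ed) +
    w[["position"]] * zscore(pairs$relative_position) +
    w[["motif"]] * (motif - mean(motif))
  efficacy <- pmin(pmax(logistic(latent) +
                          stats::rnorm(nrow(pairs), 0, config$noise_sd), 0), 1)
  pairs$efficacy <- efficacy
  truth <- list(weights = as.list(w), noise_sd = config$noise_sd,
                seed = config$seed,
                covariates = list(gc = gc, thermo_end_differential = ed,
                                  relative_position = pairs$relative_position,
                                  motif = motif, latent = latent))
  pairs <- pairs[, c("sirna_id", "sequence", "mrna_id", "target_start",
                     "efficacy")]
  dataset <- sirna_dataset(pairs, mrnas)
  attr(dataset, "truth") <- truth

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_pairs(dataset, file.path(dir, "pairs.tsv"),
                file.path(dir, "mrnas.fasta"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  dataset
}
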