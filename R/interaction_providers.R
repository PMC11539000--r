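#' Construct an RNA-protein interaction probability provider
#'
#' The RNA-AGO2 interaction probability is a scalar node feature. Providers:
#'
#' * `"stub"` — a deterministic stand-in that maps the RNA's 4-mer
#'   composition through a fixed weight table and a logistic link. It is
#'   reproducible and bounded in `[0, 1]` but is **not** a trained
#'   RNA-protein interaction classifier; use it for simulations and tests
#'   only, and substitute file-backed probabilities from a real predictor
#'   for publication-grade work.
#' * `"file"` — reads precomputed probabilities from a TSV with columns
#'   `id, probability`, keyed by sequence id.
#'
#' @param name `"stub"` or `"file"`.
#' @param path TSV path for the file-backed provider.
#' @return An `interaction_provider` object.
#' @export
interaction_provider <- function(name = c("stub", "file"), path = NULL) {
  name <- match.arg(name)
  table <- NULL
  if (name == "file") {
    if (is.null(path)) {
      abort("The file-backed provider needs a path",
            class = "sirnagraph_config_error")
    }
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("id", "probability") %in% names(raw))) {
      abort("Interaction file must have columns id, probability",
            class = "sirnagraph_schema_error")
    }
    table <- stats::setNames(as.numeric(raw$probability), as.character(raw$id))
  }
  structure(list(name = name, table = table),
            class = c(paste0("interaction_provider_", name),
                      "interaction_provider"))
}

#' @export
print.interaction_provider <- function(x, ...) {
  cat("<interaction_provider:", x$name, ">\n")
  invisible(x)
}

# Fixed 4-mer weight table for the stub: composition-derived, favouring
# U/A-rich and mildly penalizing G-quartet-like motifs. Deterministic and
# hash-free by construction.
stub_kmer_weights <- function() {
  motifs <- apply(expand.grid(RNA_BASES, RNA_BASES, RNA_BASES, RNA_BASES)[, 4:1],
                  1, paste, collapse = "")
  gc <- vapply(motifs, function(m) {
    sum(seq_chars(m) %in% c("G", "C")) / 4
  }, numeric(1))
  u5 <- as.numeric(substr(motifs, 1, 1) == "U")
  quartet <- as.numeric(motifs %in% c("GGGG", "CCCC", "AAAA", "UUUU"))
  stats::setNames(0.9 - 1.6 * gc + 0.4 * u5 - 0.8 * quartet, motifs)
}

#' RNA-protein interaction probability for one sequence
#'
#' @param sequence RNA string (the siRNA guide or the mRNA).
#' @param id Sequence id; required by the file-backed provider.
#' @param provider An [interaction_provider()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
rna_protein_interaction <- function(sequence, id = NULL,
                                    provider = interaction_provider("stub")) {
  if (!inherits(provider, "interaction_provider")) {
    abort("Unknown interaction provider", class = "sirnagraph_config_error")
  }
  p <- if (provider$name == "file") {
    if (is.null(id) || !id %in% names(provider$table)) {
      abort(paste0("No precomputed interaction probability for id '", id, "'"),
            class = "sirnagraph_lookup_error")
    }
    unname(provider$table[[id]])
  } else {
    sequence <- normalize_rna(sequence)
    w <- stub_kmer_weights()
    counts <- kmer_count_vector(sequence, 4L)
    total <- sum(counts)
    if (total == 0) 0.5 else logistic(sum(counts * w[names(counts)]) / total)
  }
  stop_if_not_scalar_prob(p, "Interaction probability")
  p
}
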