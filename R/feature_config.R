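#' The eight feature families
#'
#' Family keys used throughout the package, in the ablation switchboard's
#' cumulative order: sequence embeddings first, then thermodynamic
#' stability, base-pairing probabilities, RNA-protein interaction,
#' positional embeddings, nucleotide frequencies, rule codes, and G/C
#' percentages.
#'
#' @export
FEATURE_FAMILIES <- c(
  "sequence_embedding",
  "thermo_profile",
  "pairing_probabilities",
  "protein_interaction",
  "positional_embedding",
  "nucleotide_frequencies",
  "rule_codes",
  "gc_percentage"
)

# Table of which family feeds which node type.
FAMILY_BY_NODE <- list(
  mrna = c("sequence_embedding", "protein_interaction", "gc_percentage",
           "pairing_probabilities"),
  sirna = c("sequence_embedding", "protein_interaction", "gc_percentage",
            "pairing_probabilities", "positional_embedding",
            "nucleotide_frequencies", "rule_codes"),
  interaction = c("thermo_profile", "pairing_probabilities")
)

#' Feature-extraction configuration
#'
#' Collects every tunable of the featurization stage. Defaults follow the
#' tuned model configuration: positional-embedding dimension 6, SVD ranks
#' 100 (mRNA), 6 (siRNA) and 50 (pair). `enabled_families` drives the
#' ablation switchboard and must always include `sequence_embedding`.
#'
#' @param enabled_families Character subset of [FEATURE_FAMILIES].
#' @param positional_embedding_dim Dimension `D` of the sinusoidal embedding.
#' @param svd_ranks Named list with ranks `mrna`, `sirna`, `pair`.
#' @param folding_engine A [fold_engine()].
#' @param interaction_provider An [interaction_provider()].
#' @param nn_table Nearest-neighbor table ([load_nn_table()]).
#' @param rule_table Rule-code table ([load_rule_table()]).
#' @param max_sirna_length Pad per-position siRNA features to this length
#'   (guides are 19-23 nt).
#' @param mrna_fold_window Optional window (nt) centered on the target site
#'   for mRNA self-folding; `NULL` folds the full sequence.
#' @param cofold_window Window (nt) of mRNA sequence centered on the target
#'   site used for the siRNA-mRNA co-fold (default 100; co-folding the full
#'   mRNA for every pair is cubic in its length).
#' @param normalize_kmers Divide k-mer counts by window counts.
#' @param end_window Terminal steps in the thermodynamic end differential.
#' @param auc_threshold Efficacy cut used when binarizing labels for AUC.
#' @return A `feature_config` object (a validated list).
#' @export
feature_config <- function(enabled_families = FEATURE_FAMILIES,
                           positional_embedding_dim = 6L,
                           svd_ranks = list(mrna = 100L, sirna = 6L, pair = 50L),
                           folding_engine = fold_engine("null"),
                           interaction_provider = sirnagraph::interaction_provider("stub"),
                           nn_table = load_nn_table(),
                           rule_table = load_rule_table(),
                           max_sirna_length = 23L,
                           mrna_fold_window = NULL,
                           cofold_window = 100L,
                           normalize_kmers = FALSE,
                           end_window = 1L,
                           auc_threshold = 0.7) {
  enabled_families <- match.arg(enabled_families, FEATURE_FAMILIES,
                                several.ok = TRUE)
  if (!"sequence_embedding" %in% enabled_families) {
    abort("sequence_embedding cannot be disabled",
          class = "sirnagraph_config_error")
  }
  stopifnot(positional_embedding_dim >= 2,
            all(c("mrna", "sirna", "pair") %in% names(svd_ranks)))
  structure(
    list(
      enabled_families = enabled_families,
      positional_embedding_dim = as.integer(positional_embedding_dim),
      svd_ranks = lapply(svd_ranks, as.integer),
      folding_engine = folding_engine,
      interaction_provider = interaction_provider,
      nn_table = nn_table,
      rule_table = rule_table,
      max_sirna_length = as.integer(max_sirna_length),
      mrna_fold_window = mrna_fold_window,
      cofold_window = as.integer(cofold_window),
      normalize_kmers = isTRUE(normalize_kmers),
      end_window = as.integer(end_window),
      auc_threshold = auc_threshold
    ),
    class = "feature_config"
  )
}

#' @export
print.feature_config <- function(x, ...) {
  cat("<feature_config>\n")
  cat("  families: ", paste(x$enabled_families, collapse = ", "), "\n", sep = "")
  cat("  svd ranks: mrna ", x$svd_ranks$mrna, ", sirna ", x$svd_ranks$sirna,
      ", pair ", x$svd_ranks$pair, "\n", sep = "")
  cat("  positional dim: ", x$positional_embedding_dim,
      "; folding engine: ", x$folding_engine$name,
      "; provider: ", x$interaction_provider$name, "\n", sep = "")
  invisible(x)
}

#' Read a feature/model configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [feature_config()] and
#' [model_config()] (`features:` and `model:` blocks). Engine and provider
#' are given by name (`folding_engine: null_engine|vienna`,
#' `interaction_provider: stub` or a path).
#'
#' @param path YAML file path.
#' @return List with elements `features` and `model`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  f <- y$features %||% list()
  engine <- switch(f$folding_engine %||% "null_engine",
                   null_engine = fold_engine("null"),
                   vienna = fold_engine("vienna"),
                   abort("Unknown folding engine in config",
                         class = "sirnagraph_config_error"))
  prov <- f$interaction_provider %||% "stub"
  provider <- if (identical(prov, "stub")) {
    interaction_provider("stub")
  } else {
    interaction_provider("file", path = prov)
  }
  fc_args <- f[intersect(names(f), c("enabled_families", "positional_embedding_dim",
                                     "svd_ranks", "max_sirna_length",
                                     "mrna_fold_window", "cofold_window",
                                     "normalize_kmers", "end_window",
                                     "auc_threshold"))]
  fc <- do.call(feature_config,
                c(fc_args, list(folding_engine = engine,
                                interaction_provider = provider)))
  mc <- do.call(model_config, y$model %||% list())
  list(features = fc, model = mc)
}
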