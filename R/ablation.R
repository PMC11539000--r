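#' Cumulative feature-family ablation
#'
#' Trains one model per cumulative feature set on the same split and seed:
#' the first set contains the first two families of `family_order`
#' (sequence embeddings plus thermodynamic stability under the default
#' order) and each subsequent row adds the next family, ending with all
#' eight. Reports held-out PCC per row, so a monotone feature contribution
#' shows up as a non-decreasing column.
#'
#' @param dataset A [sirna_dataset()].
#' @param split A [grouped_split()] result reused across rows.
#' @param base_features Base [feature_config()] (its `enabled_families` is
#'   overridden per row).
#' @param base_model [model_config()] shared by every row.
#' @param family_order Permutation of [FEATURE_FAMILIES] defining the
#'   cumulative scheme.
#' @param metric_on `"test"` (default) or `"validation"`.
#' @return Tibble with one row per cumulative set: `n_families`,
#'   `families`, `pcc`, `mse`.
#' @export
run_ablation <- function(dataset, split, base_features = feature_config(),
                         base_model = model_config(),
                         family_order = FEATURE_FAMILIES,
                         metric_on = c("test", "validation")) {
  metric_on <- match.arg(metric_on)
  if (!setequal(family_order, FEATURE_FAMILIES)) {
    abort("family_order must be a permutation of FEATURE_FAMILIES",
          class = "sirnagraph_parameter_error")
  }
  if (family_order[1] != "sequence_embedding") {
    abort("The cumulative scheme must start from sequence_embedding",
          class = "sirnagraph_parameter_error")
  }
  eval_ids <- if (metric_on == "test") split$test_ids else split$val_ids
  rows <- lapply(2:length(family_order), function(k) {
    fams <- family_order[seq_len(k)]
    fc <- base_features
    fc$enabled_families <- fams
    graph <- build_graph(dataset, fc)
    fit <- train_sirna_sage(graph, split$train_ids, split$val_ids, base_model)
    preds <- predict(fit, graph, eval_ids)
    y <- graph$labels[match(eval_ids, graph$pair_ids)]
    tibble(n_families = k, families = paste(fams, collapse = "+"),
           pcc = pcc(preds$.pred, y), mse = mean((preds$.pred - y)^2))
  })
  dplyr::bind_rows(rows)
}
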