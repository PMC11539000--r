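# Portable plain-text containers for the featurize -> train pipeline and
# the model checkpoint: directories of TSV plus a JSON header, so cached
# artifacts survive across machines and library versions.

#' Serialize a graph to a directory of plain-text files
#'
#' Writes `nodes.tsv`, `edges.tsv`, one `features_<type>.tsv` per node
#' type, and `meta.json` (feature family dims, config fingerprint).
#'
#' @param graph A [build_graph()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_graph <- function(graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(graph$nodes, file.path(dir, "nodes.tsv"), progress = FALSE)
  readr::write_tsv(graph$edges, file.path(dir, "edges.tsv"), progress = FALSE)
  for (ty in names(graph$features)) {
    m <- graph$features[[ty]]
    df <- as.data.frame(m)
    names(df) <- paste0("f", seq_len(ncol(m)))
    df <- cbind(id = rownames(m), df)
    readr::write_tsv(as_tibble(df), file.path(dir, paste0("features_", ty, ".tsv")),
                     progress = FALSE)
  }
  meta <- list(
    feature_dims = graph$feature_dims,
    pair_ids = graph$pair_ids,
    labels = graph$labels,
    config_hash = rlang::hash(graph$config[setdiff(names(graph$config),
                                                   c("folding_engine",
                                                     "interaction_provider"))]),
    enabled_families = graph$config$enabled_families
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a serialized graph
#'
#' @param dir Directory written by [write_graph()].
#' @return A `sirna_graph` (without the live config objects).
#' @export
read_graph <- function(dir) {
  nodes <- readr::read_tsv(file.path(dir, "nodes.tsv"), show_col_types = FALSE,
                           progress = FALSE)
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"), show_col_types = FALSE,
                           progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  features <- lapply(c(mrna = "mrna", sirna = "sirna",
                       interaction = "interaction"), function(ty) {
    df <- readr::read_tsv(file.path(dir, paste0("features_", ty, ".tsv")),
                          show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(df$id, NULL)
    m
  })
  structure(
    list(nodes = nodes, features = features, edges = edges,
         feature_dims = meta$feature_dims,
         labels = as.numeric(meta$labels),
         pair_ids = as.character(meta$pair_ids),
         config = list(enabled_families = meta$enabled_families,
                       config_hash = meta$config_hash)),
    class = "sirna_graph"
  )
}

#' Save a trained model as a JSON checkpoint
#'
#' The checkpoint stores a metadata header (class, hidden sizes, input
#' dims, best epoch), the weights, the fitted scalers, the config snapshot
#' and the training history — all as plain JSON.
#'
#' @param model A `sirna_sage` model.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
save_sirna_sage <- function(model, path) {
  ser_mat <- function(m) {
    if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
    else list(data = as.numeric(m))
  }
  payload <- list(
    header = list(class = "sirna_sage", format = 1L,
                  layer_sizes = model$config$layer_sizes,
                  input_dims = as.list(model$input_dims),
                  best_epoch = model$best_epoch),
    params = lapply(model$params, ser_mat),
    scalers = model$scalers,
    config = model$config[setdiff(names(model$config), character(0))],
    history = as.list(model$history)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_sirna_sage()].
#' @return A `sirna_sage` model.
#' @export
load_sirna_sage <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$header$class, "sirna_sage")) {
    abort("Not a sirna_sage checkpoint", class = "sirnagraph_schema_error")
  }
  params <- lapply(p$params, function(m) {
    if (length(m$dim) == 2) matrix(m$data, m$dim[1], m$dim[2]) else as.numeric(m$data)
  })
  cfg <- p$config
  mc <- model_config(layer_sizes = cfg$layer_sizes,
                     neighbor_samples = cfg$neighbor_samples,
                     dropout = cfg$dropout, batch_size = cfg$batch_size,
                     learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                     seed = cfg$seed)
  scalers <- lapply(p$scalers, function(s) {
    list(center = as.numeric(s$center), scale = as.numeric(s$scale))
  })
  structure(
    list(params = params, final_params = params, scalers = scalers,
         config = mc, history = as_tibble(p$history),
         best_epoch = p$header$best_epoch,
         input_dims = unlist(p$header$input_dims)),
    class = "sirna_sage"
  )
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit with the null
#' folding engine and stub provider: config fingerprints, seeds, package
#' version.
#'
#' @param path Output JSON path.
#' @param feature_cfg,model_cfg Config objects (optional).
#' @param seed Run seed.
#' @param extra Named list of extra fields.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, feature_cfg = NULL, model_cfg = NULL,
                           seed = NA_integer_, extra = list()) {
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("sirnagraph")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    feature_config_hash = if (!is.null(feature_cfg)) {
      rlang::hash(feature_cfg[setdiff(names(feature_cfg),
                                      c("folding_engine", "interaction_provider"))])
    },
    folding_engine = if (!is.null(feature_cfg)) feature_cfg$folding_engine$name,
    interaction_provider = if (!is.null(feature_cfg)) feature_cfg$interaction_provider$name,
    model_config = if (!is.null(model_cfg)) unclass(model_cfg)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
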