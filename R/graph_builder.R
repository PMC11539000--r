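# Per-position matrices are right-padded with zero rows to a fixed length
# and flattened row-major, so node feature vectors are fixed-width across
# guides of 19-23 nt; the true length rides along as a scalar inside the
# sequence-embedding family.
pad_flatten <- function(mat, pad_rows) {
  if (nrow(mat) < pad_rows) {
    mat <- rbind(mat, matrix(0, pad_rows - nrow(mat), ncol(mat)))
  }
  as.numeric(t(mat))
}

clip_window <- function(mrna_seq, target_start, window) {
  L <- nchar(mrna_seq)
  if (is.null(window) || window >= L) {
    return(list(seq = mrna_seq, offset = 0L))
  }
  center <- target_start + 10L
  from <- max(0L, min(center - window %/% 2L, L - window))
  list(seq = substr(mrna_seq, from + 1L, from + window), offset = from)
}

mrna_bundle <- function(id, sequence, pad_len, config, fold_seq = NULL) {
  fams <- intersect(config$enabled_families, FAMILY_BY_NODE$mrna)
  out <- list()
  if ("sequence_embedding" %in% fams) {
    out$sequence_embedding <- c(pad_flatten(one_hot_encode(sequence), pad_len),
                                nchar(sequence))
  }
  if ("protein_interaction" %in% fams) {
    out$protein_interaction <- rna_protein_interaction(
      sequence, id = id, provider = config$interaction_provider)
  }
  if ("gc_percentage" %in% fams) out$gc_percentage <- gc_percentage(sequence)
  if ("pairing_probabilities" %in% fams) {
    bpp <- fold_pairing_matrix(fold_seq %||% sequence, config$folding_engine)
    out$pairing_probabilities <- svd_reduce(bpp, config$svd_ranks$mrna)
  }
  out
}

sirna_bundle <- function(id, sequence, target_start, config) {
  fams <- intersect(config$enabled_families, FAMILY_BY_NODE$sirna)
  pad <- config$max_sirna_length
  out <- list()
  if ("sequence_embedding" %in% fams) {
    out$sequence_embedding <- c(pad_flatten(one_hot_encode(sequence), pad),
                                nchar(sequence))
  }
  if ("protein_interaction" %in% fams) {
    out$protein_interaction <- rna_protein_interaction(
      sequence, id = id, provider = config$interaction_provider)
  }
  if ("gc_percentage" %in% fams) out$gc_percentage <- gc_percentage(sequence)
  if ("pairing_probabilities" %in% fams) {
    bpp <- fold_pairing_matrix(sequence, config$folding_engine)
    out$pairing_probabilities <- svd_reduce(bpp, config$svd_ranks$sirna)
  }
  if ("positional_embedding" %in% fams) {
    out$positional_embedding <- positional_embedding(
      target_start, config$positional_embedding_dim)
  }
  if ("nucleotide_frequencies" %in% fams) {
    out$nucleotide_frequencies <- unname(
      kmer_frequencies(sequence, 5L, normalize = config$normalize_kmers))
  }
  if ("rule_codes" %in% fams) {
    out$rule_codes <- pad_flatten(rule_codes(sequence, config$rule_table), pad)
  }
  out
}

interaction_bundle <- function(sirna_seq, mrna_seq, target_start, config) {
  fams <- intersect(config$enabled_families, FAMILY_BY_NODE$interaction)
  pad_steps <- config$max_sirna_length - 1L
  out <- list()
  if ("thermo_profile" %in% fams) {
    tp <- thermo_profile(sirna_seq, config$nn_table, config$end_window)
    steps <- c(tp$dinucleotide_dG,
               rep(0, pad_steps - length(tp$dinucleotide_dG)))
    out$thermo_profile <- c(steps, tp$total_dG, tp$end_differential_dG)
  }
  if ("pairing_probabilities" %in% fams) {
    win <- clip_window(mrna_seq, target_start, config$cofold_window)
    bpp <- cofold_pairing_matrix(sirna_seq, win$seq, config$folding_engine)
    out$pairing_probabilities <- svd_reduce(bpp, config$svd_ranks$pair)
  }
  if (length(out) == 0) out <- list(.bias = 1) # keep the node featured
  out
}

#' Feature bundles for one siRNA-mRNA pair
#'
#' Computes the named feature families assigned to the mRNA node, the siRNA
#' node, and the interaction node of one pair: the mRNA node carries its
#' sequence embedding, RNA-protein interaction probability, G/C percentage
#' and self-fold SVD features; the siRNA node additionally carries the
#' positional embedding, nucleotide frequencies and rule codes; the
#' interaction node carries the thermodynamic stability profile and the
#' co-fold SVD features. Families absent from
#' `config$enabled_families` are omitted (the ablation switchboard).
#'
#' @param pair One-row pair tibble (`sirna_id, sequence, mrna_id,
#'   target_start, efficacy`).
#' @param mrnas mRNA tibble.
#' @param config A [feature_config()].
#' @param mrna_pad Pad length for the mRNA one-hot (default: this mRNA's
#'   length).
#' @return List with elements `mrna`, `sirna`, `interaction`, each a named
#'   list of numeric vectors.
#' @export
assign_features <- function(pair, mrnas, config = feature_config(),
                            mrna_pad = NULL) {
  stopifnot(nrow(pair) == 1)
  m <- mrnas[match(pair$mrna_id, mrnas$id), ]
  if (is.na(m$id[1])) {
    abort(paste0("Unknown mrna_id: ", pair$mrna_id),
          class = "sirnagraph_reference_error")
  }
  mseq <- clip_window(m$sequence, pair$target_start, config$mrna_fold_window)
  list(
    mrna = mrna_bundle(m$id, m$sequence, mrna_pad %||% nchar(m$sequence),
                       config, fold_seq = mseq$seq),
    sirna = sirna_bundle(pair$sirna_id, pair$sequence, pair$target_start, config),
    interaction = interaction_bundle(pair$sequence, m$sequence,
                                     pair$target_start, config)
  )
}

concat_bundle <- function(bundle) {
  unlist(bundle, use.names = FALSE)
}

#' Build the heterogeneous siRNA-mRNA graph
#'
#' One node per distinct mRNA, one per distinct siRNA, and one interaction
#' node per pair; undirected edges connect each interaction node to its
#' siRNA and its mRNA (degree exactly 2, no direct siRNA-mRNA edges).
#' Efficacy labels sit on interaction nodes. Feature extraction runs once
#' per distinct entity, so shared mRNA features are computed once.
#'
#' @param dataset A [sirna_dataset()].
#' @param config A [feature_config()].
#' @return A `sirna_graph`: list with `nodes` (tibble: `node_id, type,
#'   label`), `features` (per-type numeric matrices, rows named by id),
#'   `edges` (tibble: `interaction, sirna, mrna` row indices),
#'   `feature_dims` (named family -> length, per type), and the config.
#' @export
build_graph <- function(dataset, config = feature_config()) {
  pairs <- dataset$pairs
  mrnas <- dataset$mrnas
  if (anyDuplicated(paste(pairs$sirna_id, pairs$mrna_id))) {
    abort("Duplicate siRNA-mRNA pair", class = "sirnagraph_duplication_error")
  }
  mrna_pad <- max(mrnas$length)

  mrna_feats <- lapply(seq_len(nrow(mrnas)), function(j) {
    fold_seq <- clip_window(mrnas$sequence[j], 0L, config$mrna_fold_window)$seq
    mrna_bundle(mrnas$id[j], mrnas$sequence[j], mrna_pad, config,
                fold_seq = fold_seq)
  })
  sirna_feats <- lapply(seq_len(nrow(pairs)), function(i) {
    sirna_bundle(pairs$sirna_id[i], pairs$sequence[i], pairs$target_start[i],
                 config)
  })
  int_feats <- lapply(seq_len(nrow(pairs)), function(i) {
    m <- mrnas$sequence[match(pairs$mrna_id[i], mrnas$id)]
    interaction_bundle(pairs$sequence[i], m, pairs$target_start[i], config)
  })

  to_matrix <- function(bundles, ids) {
    mat <- do.call(rbind, lapply(bundles, concat_bundle))
    rownames(mat) <- ids
    mat
  }
  features <- list(
    mrna = to_matrix(mrna_feats, mrnas$id),
    sirna = to_matrix(sirna_feats, pairs$sirna_id),
    interaction = to_matrix(int_feats, pairs$sirna_id)
  )
  feature_dims <- lapply(list(mrna = mrna_feats[[1]], sirna = sirna_feats[[1]],
                              interaction = int_feats[[1]]),
                         function(b) vapply(b, length, integer(1)))

  nodes <- dplyr::bind_rows(
    tibble(node_id = mrnas$id, type = "mrna", label = NA_real_),
    tibble(node_id = pairs$sirna_id, type = "sirna", label = NA_real_),
    tibble(node_id = pairs$sirna_id, type = "interaction",
           label = pairs$efficacy)
  )
  edges <- tibble(
    interaction = seq_len(nrow(pairs)),
    sirna = seq_len(nrow(pairs)),
    mrna = match(pairs$mrna_id, mrnas$id)
  )
  structure(
    list(nodes = nodes, features = features, edges = edges,
         feature_dims = feature_dims, labels = pairs$efficacy,
         pair_ids = pairs$sirna_id, config = config),
    class = "sirna_graph"
  )
}

#' @export
print.sirna_graph <- function(x, ...) {
  cat("<sirna_graph> ", nrow(x$features$mrna), " mRNA + ",
      nrow(x$features$sirna), " siRNA + ", nrow(x$features$interaction),
      " interaction nodes, ", 2L * nrow(x$edges), " undirected edges\n", sep = "")
  dims <- vapply(x$features, ncol, integer(1))
  cat("  feature dims: mrna ", dims[["mrna"]], ", sirna ", dims[["sirna"]],
      ", interaction ", dims[["interaction"]], "\n", sep = "")
  invisible(x)
}

# z-score scaler fitted on the training nodes only (entities incident to
# training pairs); zero-variance columns keep scale 1.
fit_scaler <- function(mat, rows) {
  sub <- mat[rows, , drop = FALSE]
  center <- colMeans(sub)
  scale <- apply(sub, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(mat, scaler) {
  sweep(sweep(mat, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

fit_graph_scalers <- function(graph, train_idx) {
  train_mrna <- unique(graph$edges$mrna[train_idx])
  list(
    mrna = fit_scaler(graph$features$mrna, train_mrna),
    sirna = fit_scaler(graph$features$sirna, train_idx),
    interaction = fit_scaler(graph$features$interaction, train_idx)
  )
}
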