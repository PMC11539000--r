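#' Read an mRNA FASTA file into a tibble
#'
#' Sequences are uppercased and DNA `T` is mapped to RNA `U`; the alphabet is
#' restricted to `A, C, G, U, N`.
#'
#' @param path Path to a FASTA file of mRNA sequences.
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @export
read_mrna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- vapply(as.character(set), normalize_rna, character(1), what = "mRNA sequence")
  if (anyDuplicated(ids)) {
    abort("Duplicate mRNA ids in FASTA", class = "sirnagraph_schema_error")
  }
  tibble(id = unname(ids), sequence = unname(seqs), length = nchar(unname(seqs)))
}

PAIR_COLUMNS <- c("sirna_id", "sequence", "mrna_id", "target_start", "efficacy")

#' Read an siRNA-mRNA pair table
#'
#' The table must contain columns `sirna_id, sequence, mrna_id, target_start`
#' and optionally `efficacy`. `sequence` is the antisense (guide) strand,
#' 19-23 nt; `target_start` is the 0-based start of the target site on the
#' mRNA. Efficacy values on a percent scale (any value above 1.5) are
#' rescaled to `[0, 1]`.
#'
#' @param path Path to a TSV or CSV pair table (delimiter inferred).
#' @return A tibble with the pair columns, sequences normalized to RNA.
#' @export
read_pair_table <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(setdiff(PAIR_COLUMNS, "efficacy"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Pair table is missing required columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "sirnagraph_schema_error")
  }
  if (!"efficacy" %in% names(raw)) raw$efficacy <- NA_real_
  pairs <- dplyr::mutate(
    dplyr::select(raw, dplyr::all_of(PAIR_COLUMNS)),
    sirna_id = as.character(.data$sirna_id),
    mrna_id = as.character(.data$mrna_id),
    sequence = vapply(.data$sequence, normalize_rna, character(1),
                      what = "siRNA sequence"),
    target_start = as.integer(.data$target_start),
    efficacy = as.numeric(.data$efficacy)
  )
  eff <- pairs$efficacy
  if (any(eff > 1.5, na.rm = TRUE)) {
    inform("Efficacy values exceed 1.5; interpreting the column as percent and rescaling to [0, 1].")
    pairs$efficacy <- eff / 100
  }
  pairs
}

validate_pairs <- function(pairs, mrnas) {
  if (anyDuplicated(pairs$sirna_id)) {
    dup <- unique(pairs$sirna_id[duplicated(pairs$sirna_id)])
    abort(paste0("Duplicate sirna_id rows: ", paste(utils::head(dup, 5), collapse = ", ")),
          class = "sirnagraph_validation_error")
  }
  len <- nchar(pairs$sequence)
  if (any(len < 19 | len > 23)) {
    abort("siRNA antisense sequences must be 19-23 nt",
          class = "sirnagraph_validation_error")
  }
  eff <- pairs$efficacy
  if (any(!is.na(eff) & (eff < 0 | eff > 1))) {
    abort("Efficacy labels must lie in [0, 1]",
          class = "sirnagraph_validation_error")
  }
  if (any(pairs$target_start < 0, na.rm = TRUE)) {
    abort("target_start must be non-negative (0-based)",
          class = "sirnagraph_validation_error")
  }
  unresolved <- setdiff(pairs$mrna_id, mrnas$id)
  if (length(unresolved) > 0) {
    abort(paste0("mrna_id not present in FASTA: ",
                 paste(utils::head(unresolved, 5), collapse = ", ")),
          class = "sirnagraph_reference_error")
  }
  mlen <- mrnas$length[match(pairs$mrna_id, mrnas$id)]
  if (any(pairs$target_start + len > mlen)) {
    abort("Target site extends past the end of the mRNA",
          class = "sirnagraph_validation_error")
  }
  invisible(pairs)
}

#' Bundle validated pair and mRNA tables into a dataset
#'
#' @param pairs Tibble with columns `sirna_id, sequence, mrna_id,
#'   target_start, efficacy`.
#' @param mrnas Tibble with columns `id, sequence, length`.
#' @return An object of class `sirna_dataset`: a list with elements `pairs`
#'   and `mrnas`.
#' @export
sirna_dataset <- function(pairs, mrnas) {
  pairs <- as_tibble(pairs)
  mrnas <- as_tibble(mrnas)
  if (!"length" %in% names(mrnas)) mrnas$length <- nchar(mrnas$sequence)
  validate_pairs(pairs, mrnas)
  structure(list(pairs = pairs, mrnas = mrnas), class = "sirna_dataset")
}

#' @export
print.sirna_dataset <- function(x, ...) {
  cat("<sirna_dataset> ", nrow(x$pairs), " pairs, ",
      length(unique(x$pairs$sirna_id)), " siRNAs, ",
      nrow(x$mrnas), " mRNAs\n", sep = "")
  n_lab <- sum(!is.na(x$pairs$efficacy))
  cat("  labelled pairs: ", n_lab, "\n", sep = "")
  invisible(x)
}

#' Load and validate an siRNA-mRNA pair dataset from disk
#'
#' Reads the pair table and mRNA FASTA, normalizes DNA to RNA alphabet,
#' resolves every `mrna_id`, and enforces the record invariants (unique
#' siRNA ids, 19-23 nt guides, efficacy in `[0, 1]`, target site inside the
#' mRNA).
#'
#' @param pair_path Path to the TSV/CSV pair table.
#' @param fasta_path Path to the mRNA FASTA.
#' @return A [sirna_dataset()] object.
#' @export
load_pairs <- function(pair_path, fasta_path) {
  mrnas <- read_mrna_fasta(fasta_path)
  pairs <- read_pair_table(pair_path)
  sirna_dataset(pairs, mrnas)
}

#' Write a dataset back to a pair table and FASTA
#'
#' Inverse of [load_pairs()]; round-trips exactly.
#'
#' @param dataset A [sirna_dataset()].
#' @param pair_path Output TSV path.
#' @param fasta_path Output FASTA path.
#' @return Invisibly, the dataset.
#' @export
write_pairs <- function(dataset, pair_path, fasta_path) {
  readr::write_tsv(dataset$pairs, pair_path, progress = FALSE)
  set <- Biostrings::RNAStringSet(dataset$mrnas$sequence)
  names(set) <- dataset$mrnas$id
  Biostrings::writeXStringSet(set, fasta_path)
  invisible(dataset)
}

#' Check target-site placement for each pair
#'
#' A site is valid when the window `[target_start, target_start + L)` lies
#' within the mRNA. Real datasets contain guide/target mismatches, so a
#' sequence mismatch is not an error: a warning is emitted when the reverse
#' complement of the antisense strand differs from the mRNA window.
#'
#' @param pairs Pair tibble (or a [sirna_dataset()], in which case `mrnas`
#'   is taken from it).
#' @param mrnas mRNA tibble.
#' @param quiet Suppress the mismatch warning.
#' @return Logical vector, one entry per pair.
#' @export
validate_site <- function(pairs, mrnas = NULL, quiet = FALSE) {
  if (inherits(pairs, "sirna_dataset")) {
    mrnas <- pairs$mrnas
    pairs <- pairs$pairs
  }
  len <- nchar(pairs$sequence)
  idx <- match(pairs$mrna_id, mrnas$id)
  mlen <- mrnas$length[idx]
  ok <- !is.na(idx) & pairs$target_start >= 0 & (pairs$target_start + len) <= mlen
  n_mismatch <- 0L
  for (i in which(ok)) {
    window <- substr(mrnas$sequence[idx[i]], pairs$target_start[i] + 1L,
                     pairs$target_start[i] + len[i])
    if (rna_revcomp(pairs$sequence[i]) != window) n_mismatch <- n_mismatch + 1L
  }
  if (n_mismatch > 0 && !quiet) {
    warn(paste0(n_mismatch, " pair(s) have guide/target mismatches (reverse ",
                "complement of the antisense strand differs from the mRNA window)"))
  }
  ok
}

#' Locate an exact-match target site for a guide strand
#'
#' Convenience scan only: positions are normally inputs to the method, not
#' recomputed. Returns the 0-based start of the first window whose sequence
#' equals the reverse complement of the guide, or `NA` if none.
#'
#' @param sirna_sequence Antisense (guide) strand.
#' @param mrna_sequence mRNA sequence.
#' @return Integer 0-based offset or `NA_integer_`.
#' @export
find_target_site <- function(sirna_sequence, mrna_sequence) {
  target <- rna_revcomp(normalize_rna(sirna_sequence))
  hit <- regexpr(target, normalize_rna(mrna_sequence), fixed = TRUE)
  if (hit < 0) NA_integer_ else as.integer(hit) - 1L
}
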