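#' Load a nearest-neighbor dinucleotide free-energy table
#'
#' The bundled default (`nn_rna_stack_dg37.tsv`) carries the standard
#' Watson-Crick RNA/RNA nearest-neighbor stacking free energies at 37 degC
#' (kcal/mol), keyed by the 5'->3' dinucleotide step on one strand. Any TSV
#' with columns `dinucleotide, dG_kcal_per_mol` covering all 16 dinucleotides
#' may be substituted.
#'
#' @param path TSV path; default is the bundled table.
#' @return Named numeric vector of length 16.
#' @export
load_nn_table <- function(path = system.file("extdata", "nn_rna_stack_dg37.tsv",
                                             package = "sirnagraph")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("dinucleotide", "dG_kcal_per_mol") %in% names(raw))) {
    abort("Nearest-neighbor table must have columns dinucleotide, dG_kcal_per_mol",
          class = "sirnagraph_schema_error")
  }
  tab <- stats::setNames(as.numeric(raw$dG_kcal_per_mol),
                         toupper(raw$dinucleotide))
  expected <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  missing <- setdiff(expected, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Nearest-neighbor table is missing dinucleotides: ",
                 paste(missing, collapse = ", ")),
          class = "sirnagraph_table_error")
  }
  tab[expected]
}

#' Thermodynamic stability profile of a guide strand
#'
#' Computes the nearest-neighbor free energy of every adjacent dinucleotide
#' step along the antisense strand (5'->3'), their sum (total duplex
#' stability under the pure nearest-neighbor decomposition), and the
#' 5'-vs-3' terminal differential that reflects guide-strand selection
#' asymmetry: mean delta-G of the first `end_window` step(s) minus mean
#' delta-G of the last `end_window` step(s).
#'
#' @param antisense Guide strand, length >= 2, no `N`.
#' @param nn_table Named dinucleotide -> delta-G vector ([load_nn_table()]).
#' @param end_window Number of terminal steps in the differential (default 1).
#' @return A list with `dinucleotide_dG` (length L-1), `total_dG`,
#'   `end_differential_dG`.
#' @export
thermo_profile <- function(antisense, nn_table = load_nn_table(),
                           end_window = 1L) {
  antisense <- normalize_rna(antisense)
  ch <- seq_chars(antisense)
  if (length(ch) < 2) {
    abort("Thermodynamic profile needs at least 2 nucleotides",
          class = "sirnagraph_precondition_error")
  }
  steps <- paste0(ch[-length(ch)], ch[-1])
  missing <- setdiff(unique(steps), names(nn_table))
  if (length(missing) > 0) {
    abort(paste0("Dinucleotide(s) absent from nearest-neighbor table: ",
                 paste(missing, collapse = ", ")),
          class = "sirnagraph_table_error")
  }
  dg <- unname(nn_table[steps])
  w <- min(end_window, length(dg))
  list(
    dinucleotide_dG = dg,
    total_dG = sum(dg),
    end_differential_dG = mean(dg[seq_len(w)]) -
      mean(dg[seq.int(length(dg) - w + 1L, length(dg))])
  )
}

# counts of all 4^k motifs (lexicographic A,C,G,U); windows containing N
# contribute to no motif
kmer_count_vector <- function(sequence, k) {
  Biostrings::oligonucleotideFrequency(Biostrings::RNAString(sequence), k)
}

#' k-mer frequency vector (k = 1..k_max)
#'
#' Counts every motif of size 1 through `k_max` over the alphabet
#' `(A, C, G, U)`, concatenated by k ascending then lexicographic motif
#' order: 4 + 16 + 64 + 256 + 1024 = 1364 entries at the default
#' `k_max = 5`. Windows containing `N` are skipped. Counts are raw by
#' default; `normalize = TRUE` divides each k-block by its window count
#' `L - k + 1`.
#'
#' @param sequence RNA string with `nchar(sequence) >= k_max`.
#' @param k_max Largest motif size (default 5).
#' @param normalize Return per-window frequencies instead of counts.
#' @return Named numeric vector of length `sum(4^(1:k_max))`.
#' @export
kmer_frequencies <- function(sequence, k_max = 5L, normalize = FALSE) {
  sequence <- normalize_rna(sequence)
  L <- nchar(sequence)
  if (L < k_max) {
    abort(paste0("Sequence of length ", L, " is shorter than k_max = ", k_max),
          class = "sirnagraph_length_error")
  }
  blocks <- lapply(seq_len(k_max), function(k) {
    counts <- kmer_count_vector(sequence, k)
    if (normalize) counts / (L - k + 1) else counts
  })
  out <- unlist(blocks)
  names(out) <- unlist(lapply(blocks, names))
  out
}

#' G/C percentage of a sequence
#'
#' Percent of G or C among non-`N` bases.
#'
#' @param sequence RNA string with at least one non-`N` base.
#' @return Numeric scalar in `[0, 100]`.
#' @export
gc_percentage <- function(sequence) {
  ch <- seq_chars(normalize_rna(sequence))
  known <- ch != "N"
  if (!any(known)) {
    abort("G/C content is undefined for an all-N sequence",
          class = "sirnagraph_validation_error")
  }
  100 * sum(ch %in% c("G", "C")) / sum(known)
}

#' Load a position-specific rule-code table
#'
#' The table maps (1-based guide position, nucleotide) to a code in
#' `{-1, 0, +1}`: +1 marks a nucleotide preference that enhances silencing
#' at that position, -1 one that impairs it, and uncovered combinations
#' default to 0. The bundled default encodes widely used design
#' preferences (5'-antisense A/U, 3'-terminal G/C, and a central-U
#' preference) and is meant to be edited or replaced.
#'
#' @param path TSV with columns `position, nucleotide, code`; default is the
#'   bundled table.
#' @return Tibble with those columns.
#' @export
load_rule_table <- function(path = system.file("extdata", "rule_codes_default.tsv",
                                               package = "sirnagraph")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("position", "nucleotide", "code") %in% names(raw))) {
    abort("Rule table must have columns position, nucleotide, code",
          class = "sirnagraph_schema_error")
  }
  raw$position <- as.integer(raw$position)
  raw$nucleotide <- toupper(as.character(raw$nucleotide))
  raw$code <- as.integer(raw$code)
  if (any(!raw$code %in% c(-1L, 0L, 1L)) || any(raw$position < 1L) ||
      any(!raw$nucleotide %in% RNA_BASES)) {
    abort("Rule table codes must be in {-1, 0, 1} with positions >= 1 and ACGU nucleotides",
          class = "sirnagraph_schema_error")
  }
  as_tibble(raw[, c("position", "nucleotide", "code")])
}

#' Position-specific rule codes of a guide strand
#'
#' Looks up each position/nucleotide in the rule table and expands the code
#' to a 3-way one-hot row: `-1 -> (1,0,0)`, `0 -> (0,1,0)`, `+1 -> (0,0,1)`.
#'
#' @param antisense Guide strand.
#' @param rule_table Tibble from [load_rule_table()] (or an empty tibble for
#'   the all-neutral encoding).
#' @return `L x 3` binary matrix, one-hot per row.
#' @export
rule_codes <- function(antisense, rule_table = load_rule_table()) {
  antisense <- normalize_rna(antisense)
  ch <- seq_chars(antisense)
  codes <- integer(length(ch))
  if (nrow(rule_table) > 0) {
    key <- paste(rule_table$position, rule_table$nucleotide)
    hit <- match(paste(seq_along(ch), ch), key)
    codes[!is.na(hit)] <- rule_table$code[hit[!is.na(hit)]]
  }
  out <- matrix(0L, length(ch), 3L,
                dimnames = list(NULL, c("impair", "neutral", "enhance")))
  out[cbind(seq_along(ch), codes + 2L)] <- 1L
  out
}
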