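#' One-hot sequence embedding
#'
#' Each base maps to a 4-dimensional indicator in column order `(A, C, G, U)`
#' (`U` occupies the slot a DNA encoding writes as `T`); ambiguous `N` maps
#' to the all-zero row.
#'
#' @param sequence RNA string over `A, C, G, U, N`.
#' @return `L x 4` binary matrix with columns `A, C, G, U`; rows follow
#'   5'->3' order.
#' @export
one_hot_encode <- function(sequence) {
  sequence <- normalize_rna(sequence)
  ch <- seq_chars(sequence)
  out <- matrix(0L, length(ch), 4L, dimnames = list(NULL, RNA_BASES))
  idx <- match(ch, RNA_BASES)
  known <- !is.na(idx)
  out[cbind(which(known), idx[known])] <- 1L
  out
}

#' Sinusoidal positional embedding of a target-site position
#'
#' Encodes the 0-based start position `i` of the siRNA on its mRNA into a
#' `D`-dimensional vector: channel `j = 2k` holds
#' `sin(i / 10000^(2k/(D-1)))` and channel `j = 2k+1` holds
#' `cos(i / 10000^(2k/(D-1)))` (channels 0-based).
#'
#' @param i Non-negative 0-based position on the mRNA.
#' @param D Embedding dimension, >= 2 (default 6).
#' @return Numeric vector of length `D`, entries in `[-1, 1]`.
#' @export
positional_embedding <- function(i, D = 6L) {
  if (length(i) != 1L || is.na(i) || i < 0) {
    abort("Position i must be a single non-negative number",
          class = "sirnagraph_parameter_error")
  }
  if (D < 2) {
    abort("Embedding dimension D must be >= 2", class = "sirnagraph_parameter_error")
  }
  j <- seq_len(D) - 1L
  k <- j %/% 2L
  angle <- i / 10000^(2 * k / (D - 1))
  ifelse(j %% 2L == 0L, sin(angle), cos(angle))
}
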