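#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Reverse complement of an RNA string
#'
#' @param sequence RNA string over A/C/G/U/N.
#' @return The reverse complement, 5'->3'.
#' @examples
#' rna_revcomp("AUGC") # "GCAU"
#' @export
rna_revcomp <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  rc <- chartr("ACGUN", "UGCAN", sequence)
  paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
}

# Uppercase, map DNA T -> RNA U, check alphabet. Returns normalized string.
normalize_rna <- function(sequence, what = "sequence") {
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), c(RNA_BASES, "N"))
  if (length(bad) > 0) {
    abort(
      paste0("Invalid characters in ", what, ": ", paste(bad, collapse = ", ")),
      class = "sirnagraph_alphabet_error"
    )
  }
  s
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

logistic <- function(x) 1 / (1 + exp(-x))

# z-score with guard for zero variance
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

stop_if_not_scalar_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort(paste0(what, " must be a probability in [0, 1], got ", format(p)),
          class = "sirnagraph_contract_error")
  }
  invisible(p)
}
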