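#' Construct a folding engine
#'
#' A folding engine turns RNA sequences into symmetric base-pair probability
#' matrices. Two engines ship with the package:
#'
#' * `"null"` — a deterministic engine that derives structured
#'   pseudo-probabilities from Watson-Crick/wobble complementarity with a
#'   stacking bonus. It needs no external binary and is the default for
#'   tests and simulations; it is not a thermodynamic model.
#' * `"vienna"` — shells out to the ViennaRNA `RNAfold`/`RNAcofold` tools
#'   (`-p`, partition function) and parses the pair probabilities from the
#'   dot-plot output.
#'
#' @param name `"null"` or `"vienna"`.
#' @param rnafold,rnacofold Executable names/paths for the vienna engine.
#' @return A `fold_engine` object.
#' @export
fold_engine <- function(name = c("null", "vienna"),
                        rnafold = "RNAfold", rnacofold = "RNAcofold") {
  name <- match.arg(name)
  structure(
    list(name = name, rnafold = rnafold, rnacofold = rnacofold),
    class = c(paste0("fold_engine_", name), "fold_engine")
  )
}

#' @export
print.fold_engine <- function(x, ...) {
  cat("<fold_engine:", x$name, ">\n")
  invisible(x)
}

check_pairing_matrix <- function(mat, tol = 1e-9) {
  if (any(mat < -tol) || any(mat > 1 + tol)) {
    abort("Pairing matrix entries must lie in [0, 1]",
          class = "sirnagraph_provider_error")
  }
  if (max(abs(mat - t(mat))) > tol) {
    abort("Pairing matrix must be symmetric",
          class = "sirnagraph_provider_error")
  }
  mat
}

#' Base-pair probability matrix of a single sequence
#'
#' @param sequence RNA string, length >= 3.
#' @param engine A [fold_engine()].
#' @return An `n x n` symmetric matrix of pair probabilities with attribute
#'   `source = "self"`.
#' @export
fold_pairing_matrix <- function(sequence, engine = fold_engine("null")) {
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) < 3) {
    abort("Folding requires a sequence of length >= 3",
          class = "sirnagraph_precondition_error")
  }
  mat <- UseMethod_fold(engine, sequence)
  structure(check_pairing_matrix(mat), source = "self")
}

UseMethod_fold <- function(engine, sequence) {
  if (inherits(engine, "fold_engine_null")) {
    null_engine_bpp(sequence)
  } else if (inherits(engine, "fold_engine_vienna")) {
    vienna_fold_bpp(engine, sequence)
  } else {
    abort("Unknown folding engine", class = "sirnagraph_config_error")
  }
}

#' Co-fold base-pair probability matrix of an siRNA-mRNA duplex
#'
#' The matrix spans the concatenated duplex: rows/columns `1..n_s` are siRNA
#' positions, `n_s+1 .. n_s+n_m` are mRNA positions.
#'
#' @param sirna,mrna RNA strings; both non-empty, total length >= 3.
#' @param engine A [fold_engine()].
#' @return A symmetric `(n_s+n_m) x (n_s+n_m)` probability matrix with
#'   attributes `source = "cofold"` and `n_first = nchar(sirna)`.
#' @export
cofold_pairing_matrix <- function(sirna, mrna, engine = fold_engine("null")) {
  sirna <- normalize_rna(sirna)
  mrna <- normalize_rna(mrna)
  if (nchar(sirna) == 0 || nchar(mrna) == 0) {
    abort("Co-folding requires two non-empty sequences",
          class = "sirnagraph_precondition_error")
  }
  mat <- if (inherits(engine, "fold_engine_null")) {
    null_engine_bpp(paste0(sirna, mrna), boundary = nchar(sirna))
  } else if (inherits(engine, "fold_engine_vienna")) {
    vienna_cofold_bpp(engine, sirna, mrna)
  } else {
    abort("Unknown folding engine", class = "sirnagraph_config_error")
  }
  structure(check_pairing_matrix(mat), source = "cofold", n_first = nchar(sirna))
}

# Deterministic pseudo-probabilities from complementarity.
# Pair scores: GC 0.6, AU 0.35, GU 0.2; positions closer than the minimum
# hairpin loop (3 unpaired bases) within one molecule cannot pair; a stack
# bonus rewards pairs whose diagonal neighbors can also pair; finally the
# matrix is scaled so no row sums above 1.
null_engine_bpp <- function(sequence, boundary = NA_integer_) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  score_of <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  score_of["A", "U"] <- score_of["U", "A"] <- 0.35
  score_of["G", "C"] <- score_of["C", "G"] <- 0.60
  score_of["G", "U"] <- score_of["U", "G"] <- 0.20
  idx <- match(ch, RNA_BASES) # N -> NA
  s <- matrix(0, n, n)
  known <- !is.na(idx)
  s[known, known] <- score_of[cbind(
    rep(idx[known], times = sum(known)),
    rep(idx[known], each = sum(known))
  )]
  # minimum-loop constraint applies only within a molecule
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  same_mol <- if (is.na(boundary)) {
    matrix(TRUE, n, n)
  } else {
    grp <- c(rep(1L, boundary), rep(2L, n - boundary))
    outer(grp, grp, "==")
  }
  s[same_mol & d < 4] <- 0
  diag(s) <- 0
  # stack bonus from the (i-1, j+1) and (i+1, j-1) neighbors
  shift_ul <- matrix(0, n, n)
  shift_ul[2:n, 1:(n - 1)] <- s[1:(n - 1), 2:n]
  shift_lr <- matrix(0, n, n)
  shift_lr[1:(n - 1), 2:n] <- s[2:n, 1:(n - 1)]
  p <- s * (1 + (shift_ul > 0) + (shift_lr > 0)) / 3
  p <- (p + t(p)) / 2
  rs <- max(rowSums(p), 1)
  p / rs
}

run_vienna <- function(exe, input, args) {
  dir <- tempfile("vienna")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE)
  out <- tryCatch(
    system2(exe, args = args, input = input, stdout = TRUE, stderr = TRUE),
    error = function(e) {
      abort(paste0("Folding engine '", exe, "' failed: ", conditionMessage(e)),
            class = "sirnagraph_provider_error")
    }
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(paste0("Folding engine '", exe, "' exited with status ", status,
                 ": ", paste(utils::tail(out, 3), collapse = " / ")),
          class = "sirnagraph_provider_error")
  }
  dp <- list.files(dir, pattern = "_dp\\.ps$", full.names = TRUE)
  if (length(dp) != 1) {
    abort("Folding engine produced no dot plot", class = "sirnagraph_provider_error")
  }
  readLines(dp)
}

parse_dotplot <- function(lines, n) {
  mat <- matrix(0, n, n)
  ub <- grep(" ubox$", lines, value = TRUE)
  ub <- ub[grepl("^\\s*\\d", ub)]
  if (length(ub) > 0) {
    fields <- do.call(rbind, strsplit(trimws(ub), "\\s+"))
    i <- as.integer(fields[, 1])
    j <- as.integer(fields[, 2])
    p <- as.numeric(fields[, 3])^2 # dot plot stores sqrt(p)
    keep <- i >= 1 & j >= 1 & i <= n & j <= n
    mat[cbind(i[keep], j[keep])] <- p[keep]
    mat[cbind(j[keep], i[keep])] <- p[keep]
  }
  pmin(pmax(mat, 0), 1)
}

vienna_fold_bpp <- function(engine, sequence) {
  lines <- run_vienna(engine$rnafold, paste0(">q\n", sequence, "\n"),
                      c("-p", "--noPS"))
  parse_dotplot(lines, nchar(sequence))
}

vienna_cofold_bpp <- function(engine, sirna, mrna) {
  lines <- run_vienna(engine$rnacofold, paste0(">q\n", sirna, "&", mrna, "\n"),
                      c("-p", "--noPS"))
  parse_dotplot(lines, nchar(sirna) + nchar(mrna))
}

#' Reduce a pairing matrix to a fixed-length spectral feature
#'
#' The default reducer returns the top-`r` singular values of the matrix
#' (zero-padded when the matrix is smaller than `r`). Singular values are a
#' fixed-length, permutation-invariant summary, which makes the feature
#' comparable across sequences of different lengths. An alternative reducer
#' projects rows onto the top-`r` right singular vectors and mean-pools.
#'
#' @param matrix A square pairing (or any numeric) matrix.
#' @param r Target dimension, >= 1.
#' @param method `"singular_values"` (default) or `"row_project"`.
#' @return Numeric vector of length `r`. For `"singular_values"` the entries
#'   are non-increasing.
#' @export
svd_reduce <- function(matrix, r, method = c("singular_values", "row_project")) {
  method <- match.arg(method)
  if (r < 1) abort("Rank r must be >= 1", class = "sirnagraph_parameter_error")
  n <- min(dim(matrix))
  if (method == "singular_values") {
    d <- if (isSymmetric(unclass(matrix), tol = 1e-9)) {
      sort(abs(eigen(matrix, symmetric = TRUE, only.values = TRUE)$values),
           decreasing = TRUE)
    } else {
      svd(matrix, nu = 0, nv = 0)$d
    }
    out <- d[seq_len(min(r, n))]
  } else {
    k <- min(r, n)
    sv <- svd(matrix, nu = 0, nv = k)
    out <- colMeans(matrix %*% sv$v[, seq_len(k), drop = FALSE])
  }
  c(out, rep(0, r - length(out)))
}
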