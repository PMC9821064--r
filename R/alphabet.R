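#' The 20 proteinogenic residues in canonical (PAML) order
#'
#' All matrices, pair orderings and file formats in this package use the
#' residue order of the PAML amino-acid data files:
#' A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aa_residues <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' The 380 ordered substitution pairs in canonical order
#'
#' Pairs are enumerated row-major over the canonical residue order: the
#' source residue is the outer loop and the destination the inner loop,
#' skipping the diagonal. This matches the layout of the 20 x 20 ddG
#' matrix read row by row.
#'
#' @return A data frame with columns `source` and `destination`
#'   (380 rows) and row names of the form `"A>R"`.
#' @export
canonical_pairs <- function() {
  aa <- aa_residues()
  src <- rep(aa, each = 20)
  dst <- rep(aa, times = 20)
  keep <- src != dst
  out <- data.frame(source = src[keep], destination = dst[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- paste0(out$source, ">", out$destination)
  out
}

#' Flatten a 20 x 20 matrix into the canonical 380-pair vector
#'
#' Reads the off-diagonal of a residue-labelled matrix row by row (source
#' outer, destination inner), the ordering shared by all per-pair vectors in
#' the package.
#'
#' @param m 20 x 20 matrix, residue-labelled or in canonical order.
#' @return Named 380-vector (`"A>R"`, ...).
#' @export
pair_vector <- function(m) offdiagonal_vector(m)

# Flatten the off-diagonal of a residue-labelled 20x20 matrix into the
# canonical 380-vector (row-major, source outer).
offdiagonal_vector <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(20L, 20L)))
  aa <- aa_residues()
  if (!is.null(rownames(m))) m <- m[aa, aa]
  v <- as.vector(t(m))                    # row-major
  keep <- as.vector(t(diag(20) == 0))
  out <- v[keep]
  names(out) <- rownames(canonical_pairs())
  out
}

# Inverse of offdiagonal_vector(): 380-vector back to a 20x20 matrix with
# NA diagonal.
vector_to_matrix <- function(v) {
  stopifnot(length(v) == 380L)
  aa <- aa_residues()
  m <- matrix(NA_real_, 20, 20, dimnames = list(aa, aa))
  pairs <- canonical_pairs()
  m[cbind(match(pairs$source, aa), match(pairs$destination, aa))] <- v
  m
}

check_residue <- function(x, arg = "residue") {
  if (length(x) != 1L || !x %in% aa_residues())
    stop("unknown ", arg, ": ", paste(x, collapse = ","), call. = FALSE)
  invisible(x)
}
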