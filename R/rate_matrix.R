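#' @title Reversible amino-acid rate matrices from PAML-style files
#'
#' @description
#' Empirical replacement models (DSO78, JTT, LG) are distributed as a
#' symmetric exchangeability matrix S plus stationary frequencies pi. The
#' instantaneous rate matrix is Q = S * Pi (q_ij = s_ij * pi_j for i != j),
#' with the diagonal set so rows sum to zero, which satisfies detailed
#' balance pi_i q_ij = pi_j q_ji by construction. Before any comparison the
#' matrix is normalized to unit mean rate, -sum_i pi_i q_ii = 1, the usual
#' phylogenetics convention; the five fixed pre-exponential levels of the
#' Arrhenius model are only meaningful on that common scale.
#'
#' @name rate_matrices
NULL

#' Path to a bundled substitution-model file
#'
#' The package ships the canonical PAML-format data files for the Dayhoff
#' (DSO78), Jones-Taylor-Thornton (JTT) and Le-Gascuel (LG) models.
#'
#' @param name One of `"dayhoff"`, `"jones"`, `"lg"`.
#' @return File path.
#' @export
substitution_model_file <- function(name = c("dayhoff", "jones", "lg")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".dat"), package = "stabrate",
              mustWork = TRUE)
}

#' Parse a PAML-style amino-acid .dat file
#'
#' The dialect is 19 lines holding the strict lower triangle of the
#' symmetric exchangeability matrix (line k carries k values, residue order
#' A R N D C Q E G H I L K M F P S T W Y V), followed by 20 stationary
#' frequencies which may wrap over several lines. Blank lines and `#`
#' comments are tolerated; anything after the frequencies is ignored.
#' Frequencies are renormalized to sum to 1 (a message reports the raw sum
#' when it is off by more than 1e-6).
#'
#' @param text Character vector of lines, or a single file path.
#' @return List with `S` (symmetric 20 x 20 matrix, zero diagonal) and
#'   `pi` (length-20 frequency vector summing to 1), both residue-labelled.
#' @export
parse_paml_dat <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  lines <- sub("#.*$", "", text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  aa <- aa_residues()

  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  ln <- 0L
  for (row in 2:20) {
    ln <- ln + 1L
    if (ln > length(lines))
      stop("truncated file: triangle ends at line ", ln - 1L, call. = FALSE)
    vals <- suppressWarnings(as.numeric(strsplit(lines[ln], "\\s+")[[1]]))
    if (anyNA(vals))
      stop("line ", ln, ": non-numeric value in exchangeability triangle",
           call. = FALSE)
    if (length(vals) != row - 1L)
      stop("line ", ln, ": expected ", row - 1L,
           " exchangeabilities, found ", length(vals), call. = FALSE)
    if (any(vals < 0))
      stop("line ", ln, ": negative exchangeability", call. = FALSE)
    S[row, seq_len(row - 1L)] <- vals
  }
  S <- S + t(S)

  freqs <- numeric(0)
  for (fl in seq(ln + 1L, length.out = max(0L, length(lines) - ln))) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[fl], "\\s+")[[1]]))
    if (anyNA(vals)) break
    freqs <- c(freqs, vals)
    if (length(freqs) >= 20L) break
  }
  if (length(freqs) < 20L)
    stop("expected 20 stationary frequencies after the triangle, found ",
         length(freqs), call. = FALSE)
  freqs <- freqs[1:20]
  if (any(freqs < 0))
    stop("negative stationary frequency", call. = FALSE)
  total <- sum(freqs)
  if (total < 0.99 || total > 1.01)
    stop("stationary frequencies sum to ", format(total),
         ", outside [0.99, 1.01]", call. = FALSE)
  if (abs(total - 1) > 1e-6)
    message("frequencies renormalized (raw sum ", format(total), ")")
  pi <- freqs / total
  names(pi) <- aa
  list(S = S, pi = pi)
}

#' Build a reversible instantaneous rate matrix Q = S * Pi
#'
#' @param S Symmetric non-negative 20 x 20 exchangeability matrix.
#' @param pi Stationary frequencies (length 20, summing to 1).
#' @param normalize Scale the matrix to unit mean rate,
#'   `-sum(pi * diag(q)) = 1` (default TRUE).
#' @return Object of class `rate_matrix`: list with `q` (20 x 20, rows sum
#'   to zero), `pi`, and `normalized`.
#' @export
build_rate_matrix <- function(S, pi, normalize = TRUE) {
  stopifnot(all(dim(S) == c(20L, 20L)), length(pi) == 20L)
  if (max(abs(S - t(S))) > 1e-12)
    stop("exchangeability matrix must be symmetric", call. = FALSE)
  pi <- pi / sum(pi)
  q <- S * rep(pi, each = 20)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  if (normalize) {
    mu <- -sum(pi * diag(q))
    q <- q / mu
  }
  aa <- aa_residues()
  dimnames(q) <- list(aa, aa)
  names(pi) <- aa
  structure(list(q = q, pi = pi, normalized = normalize),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("Reversible amino-acid rate matrix (20 x 20)\n")
  cat("  mean rate:", format(-sum(x$pi * diag(x$q))),
      if (x$normalized) "(normalized)" else "", "\n")
  cat("  detailed-balance violation:", format(check_detailed_balance(x)), "\n")
  invisible(x)
}

#' Off-diagonal rates in canonical pair order
#'
#' @param Q `rate_matrix` object.
#' @return Named 380-vector (`"A>R"`, ...) of instantaneous rates, row-major
#'   over the canonical residue order.
#' @export
offdiagonal_rates <- function(Q) {
  stopifnot(inherits(Q, "rate_matrix"))
  offdiagonal_vector(Q$q)
}

#' Maximum detailed-balance violation of a rate matrix
#'
#' Reversibility requires pi_i q_ij = pi_j q_ji for every pair; matrices
#' built by [build_rate_matrix()] satisfy it to floating-point accuracy.
#'
#' @param Q `rate_matrix` object.
#' @return Non-negative scalar, the largest absolute violation.
#' @export
check_detailed_balance <- function(Q) {
  stopifnot(inherits(Q, "rate_matrix"))
  flux <- Q$pi * Q$q
  max(abs(flux - t(flux)))
}

#' Read a bundled empirical model as a normalized rate matrix
#'
#' @param name One of `"dayhoff"`, `"jones"`, `"lg"`.
#' @param normalize Passed to [build_rate_matrix()].
#' @return `rate_matrix` object.
#' @export
empirical_rate_matrix <- function(name = c("dayhoff", "jones", "lg"),
                                  normalize = TRUE) {
  parsed <- parse_paml_dat(substitution_model_file(name))
  build_rate_matrix(parsed$S, parsed$pi, normalize = normalize)
}

#' Export a rate matrix and its frequencies to CSV
#'
#' Writes `<stem>_q.csv` (20 x 20 rates) and `<stem>_pi.csv` (frequencies).
#'
#' @param Q `rate_matrix` object.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_rate_matrix <- function(Q, stem) {
  stopifnot(inherits(Q, "rate_matrix"))
  qp <- paste0(stem, "_q.csv")
  pp <- paste0(stem, "_pi.csv")
  utils::write.csv(as.data.frame(Q$q), qp, row.names = TRUE)
  utils::write.csv(data.frame(residue = names(Q$pi), pi = Q$pi,
                              row.names = NULL), pp, row.names = FALSE)
  invisible(c(qp, pp))
}
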