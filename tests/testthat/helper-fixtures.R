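# Shared helpers for the test suite.

# A complete, asymmetric, deterministic 20x20 ddG-like matrix (NA diagonal).
toy_ddg <- function() {
  aa <- aa_residues()
  m <- outer(seq_len(20), seq_len(20),
             function(i, j) round(0.3 * (j - i) + 0.07 * i * j %% 3 - 0.5, 2))
  dimnames(m) <- list(aa, aa)
  diag(m) <- NA_real_
  m
}

# Minimal PAML dat text: all exchangeabilities `s`, uniform frequencies.
uniform_dat_lines <- function(s = 1) {
  tri <- vapply(1:19, function(k) paste(rep(s, k), collapse = " "),
                character(1))
  c(tri, "", paste(rep(0.05, 20), collapse = " "))
}

# Independent brute-force minimum nucleotide distance between two residues,
# written against Biostrings' code table directly (oracle for min_changes).
brute_min_changes <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  ca <- names(gc)[gc == a]
  cb <- names(gc)[gc == b]
  best <- 3L
  for (x in ca) for (y in cb) {
    d <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    best <- min(best, d)
  }
  best
}
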