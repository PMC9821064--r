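#' @title Standard genetic code utilities and substitution-pair features
#'
#' @description
#' The pre-exponential factor of the Arrhenius substitution model collects
#' everything that affects the rate of the underlying codon mutations, so the
#' structure of the standard genetic code is its natural explanatory
#' variable. This file derives, for every ordered pair of residues, ten
#' numeric features of the code: codon-count differences and products,
#' transition/transversion composition of all codon-to-codon comparisons,
#' minimal nucleotide distances, and GC-content differences.
#'
#' @name genetic_code
NULL

# Sense codons of the standard nuclear code (NCBI transl_table=1), keyed by
# residue. Built once from Biostrings' genetic code constant; stop codons are
# excluded.
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      sense <- gc[gc != "*"]
      tab <<- split(names(sense), factor(unname(sense), levels = aa_residues()))
    }
    tab
  }
})

#' Sense codons of a residue under the standard genetic code
#'
#' @param residue One-letter residue code.
#' @return Character vector of codons (DNA alphabet).
#' @examples
#' codons_for("M")  # "ATG"
#' codons_for("L")  # six codons
#' @export
codons_for <- function(residue) {
  check_residue(residue)
  codon_table()[[residue]]
}

#' Classify a nucleotide change as transition or transversion
#'
#' A transition exchanges two purines (A, G) or two pyrimidines (C, T);
#' every other change is a transversion.
#'
#' @param base_a,base_b Distinct bases in `c("A","C","G","T")`.
#' @return `"transition"` or `"transversion"`.
#' @export
classify_nucleotide_change <- function(base_a, base_b) {
  bases <- c("A", "C", "G", "T")
  if (!base_a %in% bases || !base_b %in% bases)
    stop("bases must be one of A, C, G, T", call. = FALSE)
  if (base_a == base_b)
    stop("bases must differ", call. = FALSE)
  purine <- c("A", "G")
  if ((base_a %in% purine) == (base_b %in% purine)) "transition" else "transversion"
}

# GC fraction of a codon (0, 1/3, 2/3 or 1).
codon_gc <- function(codon) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  sum(chars %in% c("G", "C")) / 3
}

# Positionwise comparison of two codons: number of differences and how many
# of them are transitions.
codon_diff <- function(c1, c2) {
  a <- strsplit(c1, "", fixed = TRUE)[[1]]
  b <- strsplit(c2, "", fixed = TRUE)[[1]]
  idx <- which(a != b)
  ts <- sum(vapply(idx, function(k)
    classify_nucleotide_change(a[k], b[k]) == "transition", logical(1)))
  c(changes = length(idx), transitions = ts)
}

#' Genetic-code features of one ordered substitution pair
#'
#' Computes the ten code-derived predictors for a substitution
#' `source -> destination`:
#'
#' * `diffcodon`: codon count of the destination minus that of the source.
#' * `ccodon`: product of the two codon counts, i.e. the number of
#'   codon-to-codon comparisons considered below.
#' * `transitions`, `transversions`: transition and transversion changes
#'   counted over all `ccodon` codon pairs, each divided by the total number
#'   of nucleotide differences across those pairs (they sum to 1).
#' * `min_changes`: the smallest number of nucleotide changes over the
#'   `ccodon` codon pairs (1 for "singlet" pairs).
#' * `min_transitions`, `min_transversions`: among the codon pairs that
#'   achieve `min_changes`, the minimal number of transition (resp.
#'   transversion) changes.
#' * `meanGC`, `minGC`, `maxGC`: mean, minimum and maximum over codon pairs
#'   of the GC-fraction difference (destination codon minus source codon).
#'
#' @param source,destination Distinct one-letter residue codes.
#' @return Named numeric vector of the ten features.
#' @examples
#' substitution_features("I", "M")  # diffcodon -2, min_changes 1
#' @export
substitution_features <- function(source, destination) {
  check_residue(source, "source")
  check_residue(destination, "destination")
  if (source == destination)
    stop("source and destination must differ", call. = FALSE)
  cs <- codons_for(source)
  cd <- codons_for(destination)
  n_pairs <- length(cs) * length(cd)

  changes <- matrix(0, n_pairs, 2)
  gcdiff <- numeric(n_pairs)
  k <- 1L
  for (a in cs) for (b in cd) {
    changes[k, ] <- codon_diff(a, b)
    gcdiff[k] <- codon_gc(b) - codon_gc(a)
    k <- k + 1L
  }
  total <- sum(changes[, 1])
  ts_total <- sum(changes[, 2])
  min_ch <- min(changes[, 1])
  at_min <- changes[, 1] == min_ch

  c(diffcodon       = length(cd) - length(cs),
    ccodon          = n_pairs,
    transitions     = ts_total / total,
    transversions   = (total - ts_total) / total,
    min_changes     = min_ch,
    min_transitions = min(changes[at_min, 2]),
    min_transversions = min(changes[at_min, 1] - changes[at_min, 2]),
    meanGC          = mean(gcdiff),
    minGC           = min(gcdiff),
    maxGC           = max(gcdiff))
}

#' Feature table for all 380 ordered substitution pairs
#'
#' Applies [substitution_features()] to every ordered pair in canonical
#' order. The result is a pure function of the standard genetic code.
#'
#' @return Data frame of 380 rows (named `"A>R"`, ...) and 10 feature
#'   columns.
#' @export
feature_table <- function() {
  pairs <- canonical_pairs()
  feats <- t(mapply(substitution_features, pairs$source, pairs$destination))
  out <- as.data.frame(feats)
  rownames(out) <- rownames(pairs)
  out
}
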