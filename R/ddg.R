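#' @title Stability-change (ddG) matrices and their summaries
#'
#' @description
#' Site-level mutational-scan output (one ddG value per site and destination
#' residue) is summarized into an asymmetric 20 x 20 matrix of median ddG
#' values, rows = source residue, columns = destination residue, in kcal/mol.
#' Positive entries destabilize the protein. The diagonal is undefined (NA).
#' This file also provides the bundled proteome-scale median matrix, the
#' energy-barrier transform E = |ddG|, the source/destination rank
#' association, conservative-vs-radical labelling, and the disease-potential
#' regression.
#'
#' @name ddg_stability
NULL

# md5 of the bundled median-ddG fixture, to detect silent corruption.
DDG_FIXTURE_MD5 <- "02b28502c5fd72ec101e9d1dd56cfb9b"

#' Read a site-scan table
#'
#' Accepts either the long format with header columns
#' `protein, position, wt, mut, ddg` (comma- or tab-separated), or a wide
#' FoldX-like format with columns `protein, position, wt` followed by 19
#' destination-residue columns, which is normalized to long format on read.
#'
#' @param path File path.
#' @return Data frame with columns `protein`, `position`, `wt`, `mut`,
#'   `ddg`.
#' @export
read_site_scans <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (all(c("mut", "ddg") %in% names(df))) {
    return(df[, c("protein", "position", "wt", "mut", "ddg")])
  }
  dest_cols <- intersect(aa_residues(), names(df))
  if (length(dest_cols) < 19L)
    stop("unrecognized site-scan format: ", path, call. = FALSE)
  long <- do.call(rbind, lapply(dest_cols, function(aa) {
    data.frame(protein = df$protein, position = df$position, wt = df$wt,
               mut = aa, ddg = df[[aa]], stringsAsFactors = FALSE)
  }))
  long[long$wt != long$mut & !is.na(long$ddg), ]
}

#' Write a site-scan table (long format)
#'
#' @param scans Data frame as returned by [read_site_scans()].
#' @param path Output path; tab-separated with header.
#' @export
write_site_scans <- function(scans, path) {
  utils::write.table(scans[, c("protein", "position", "wt", "mut", "ddg")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Summarize site-level ddG scans into a 20 x 20 median matrix
#'
#' Entry (i, j) is the median of all ddG values with wild-type residue i and
#' destination residue j, pooled over proteins and positions. Ordered pairs
#' with no observations are reported as NA (missing is flagged, never
#' imputed). Rows with non-finite ddG are dropped with a warning.
#'
#' @param scans Site-scan data frame (`protein`, `position`, `wt`, `mut`,
#'   `ddg`).
#' @return 20 x 20 numeric matrix with residue dimnames and NA diagonal.
#' @export
summarize_site_scans <- function(scans) {
  if (is.null(scans) || nrow(scans) == 0L)
    stop("empty site-scan table", call. = FALSE)
  bad <- !is.finite(scans$ddg)
  if (any(bad)) {
    warning(sum(bad), " rows with non-finite ddg dropped")
    scans <- scans[!bad, ]
  }
  aa <- aa_residues()
  med <- tapply(scans$ddg,
                list(factor(scans$wt, levels = aa),
                     factor(scans$mut, levels = aa)),
                stats::median)
  m <- matrix(as.numeric(med), 20, 20, dimnames = list(aa, aa))
  diag(m) <- NA_real_
  m
}

#' Read / write a residue-labelled 20 x 20 ddG matrix
#'
#' CSV with residue row and column labels in canonical order; `#` lines are
#' treated as comments. The diagonal is NA.
#'
#' @param path File path.
#' @return 20 x 20 numeric matrix.
#' @export
read_ddg_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, comment.char = "#",
                        check.names = FALSE)
  m <- as.matrix(df)
  aa <- aa_residues()
  if (!identical(rownames(m), aa) || !identical(colnames(m), aa))
    stop("ddG matrix must be labelled with the 20 residues in canonical order",
         call. = FALSE)
  m
}

#' @rdname read_ddg_matrix
#' @param ddg Matrix to write.
#' @export
write_ddg_matrix <- function(ddg, path) {
  utils::write.csv(as.data.frame(ddg), path, row.names = TRUE)
}

#' The bundled proteome-scale median ddG matrix
#'
#' Median stability change (kcal/mol) for each of the 380 ordered
#' substitutions, aggregated from a FoldX mutational scan of 14,094 human
#' proteins (7,214,402 sites x 19 destination residues). Rows are the source
#' residue, columns the destination. One typographic repair relative to the
#' printed source is documented in the fixture header (W->V transcribed as
#' 2.30).
#'
#' @param check Verify the fixture checksum before reading (default TRUE).
#' @return 20 x 20 numeric matrix with NA diagonal.
#' @export
ddg_human_proteome <- function(check = TRUE) {
  path <- system.file("extdata", "ddg_median_human_proteome.csv",
                      package = "stabrate", mustWork = TRUE)
  if (check) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, DDG_FIXTURE_MD5))
      stop("ddG fixture checksum mismatch: file is corrupted", call. = FALSE)
  }
  read_ddg_matrix(path)
}

#' Energy barrier of each substitution
#'
#' The Arrhenius energy barrier opposing a substitution is the absolute
#' value of its median stability change, E = |ddG|: strongly stabilizing
#' changes are treated as barriers too, since large stability shifts in
#' either direction are selected against.
#'
#' @param ddg 20 x 20 ddG matrix, complete off-diagonal.
#' @return 20 x 20 non-negative matrix with NA diagonal.
#' @export
energy_barrier <- function(ddg) {
  off <- ddg[row(ddg) != col(ddg)]
  if (any(!is.finite(off)))
    stop("ddG matrix has missing off-diagonal entries", call. = FALSE)
  abs(ddg)
}

#' Rank association between source and destination destabilization
#'
#' Each residue is scored in its source role (aggregate of its 19 row
#' entries) and its destination role (aggregate of its 19 column entries).
#' Aggregation acts on the energy-barrier scale |ddG| by default, so that
#' "most destabilizing" means largest typical stability perturbation.
#' Residues are ranked least-to-most destabilizing in each role and the
#' destination ranks are regressed on the source ranks by OLS; the p-value
#' uses the t distribution with 18 degrees of freedom.
#'
#' @param ddg 20 x 20 ddG matrix.
#' @param aggregate `"mean"` (default, calibrated against the published
#'   statistics) or `"median"`.
#' @param on_barrier Aggregate |ddG| (default TRUE) rather than signed ddG.
#' @return List with `source_ranks`, `destination_ranks`, `r_squared`,
#'   `p_value` and `slope_sign`.
#' @export
rank_association <- function(ddg, aggregate = c("mean", "median"),
                             on_barrier = TRUE) {
  aggregate <- match.arg(aggregate)
  f <- match.fun(aggregate)
  m <- if (on_barrier) abs(ddg) else ddg
  src <- apply(m, 1, f, na.rm = TRUE)
  dst <- apply(m, 2, f, na.rm = TRUE)
  if (anyDuplicated(src) || anyDuplicated(dst))
    message("ties in role aggregates broken by canonical residue order")
  rs <- rank(src, ties.method = "first")
  rd <- rank(dst, ties.method = "first")
  fit <- summary(stats::lm(rd ~ rs))
  slope <- fit$coefficients[2, 1]
  list(source_ranks = rs,
       destination_ranks = rd,
       r_squared = fit$r.squared,
       p_value = fit$coefficients[2, 4],
       slope_sign = sign(slope))
}

#' Default physicochemical category tables
#'
#' Two-class polarity and three-class side-chain volume assignments used by
#' the polarity-volume criterion of [classify_conservative_radical()]. Both
#' are ordinary named character vectors and can be replaced by the caller.
#'
#' @return Named character vector over the 20 residues.
#' @export
default_polarity_classes <- function() {
  c(A = "nonpolar", R = "polar", N = "polar", D = "polar", C = "polar",
    Q = "polar", E = "polar", G = "nonpolar", H = "polar", I = "nonpolar",
    L = "nonpolar", K = "polar", M = "nonpolar", F = "nonpolar",
    P = "nonpolar", S = "polar", T = "polar", W = "polar", Y = "polar",
    V = "nonpolar")
}

#' @rdname default_polarity_classes
#' @export
default_volume_classes <- function() {
  # thresholds on side-chain volume: small < 120 A^3, medium < 160, large
  c(A = "small", R = "large", N = "small", D = "small", C = "small",
    Q = "medium", E = "medium", G = "small", H = "medium", I = "medium",
    L = "medium", K = "medium", M = "medium", F = "large", P = "small",
    S = "small", T = "small", W = "large", Y = "large", V = "medium")
}

#' Conservative vs radical labels under two criteria
#'
#' The energy criterion labels a pair radical when its energy barrier
#' |ddG| exceeds `energy_threshold`. The polarity-volume criterion labels a
#' pair radical when the two residues fall in different polarity classes or
#' different volume classes. The four-way agreement class records how the
#' two criteria combine.
#'
#' @param ddg 20 x 20 ddG matrix.
#' @param energy_threshold Radical threshold in kcal/mol (default 1).
#' @param polarity_classes,volume_classes Named character vectors assigning
#'   every residue to exactly one class.
#' @return Data frame over the 380 canonical pairs with columns
#'   `energy_label`, `pv_label` and `agreement`.
#' @export
classify_conservative_radical <- function(ddg, energy_threshold = 1,
                                          polarity_classes = default_polarity_classes(),
                                          volume_classes = default_volume_classes()) {
  aa <- aa_residues()
  if (!all(aa %in% names(polarity_classes)) ||
      !all(aa %in% names(volume_classes)))
    stop("category tables must cover all 20 residues", call. = FALSE)
  pairs <- canonical_pairs()
  barrier <- offdiagonal_vector(abs(ddg))
  energy <- ifelse(barrier > energy_threshold, "radical", "conservative")
  pv <- ifelse(polarity_classes[pairs$source] != polarity_classes[pairs$destination] |
               volume_classes[pairs$source] != volume_classes[pairs$destination],
               "radical", "conservative")
  data.frame(energy_label = energy, pv_label = unname(pv),
             agreement = paste(energy, unname(pv), sep = "/"),
             row.names = rownames(pairs), stringsAsFactors = FALSE)
}

#' Regression of disease-causing potential on ddG
#'
#' The disease-causing potential of a substitution is the count of
#' disease-associated occurrences (DAR) divided by its count among common,
#' presumed-neutral polymorphisms (SAAP). Pairs with a zero count in either
#' matrix are excluded (log undefined); the log ratio is regressed on ddG by
#' OLS. A positive slope indicates destabilization-driven pathogenicity.
#'
#' @param ddg 20 x 20 ddG matrix.
#' @param dar,saap 20 x 20 non-negative count matrices (diagonal ignored).
#' @return List with `slope`, `slope_se`, `intercept`, `r_squared`,
#'   `p_value` and `n` (retained pairs).
#' @export
disease_potential_regression <- function(ddg, dar, saap) {
  x <- offdiagonal_vector(ddg)
  d <- offdiagonal_vector(dar)
  s <- offdiagonal_vector(saap)
  keep <- is.finite(x) & d > 0 & s > 0
  if (sum(!keep) > 0)
    message(sum(!keep), " pairs excluded (zero or missing counts)")
  if (sum(keep) < 3L)
    stop("fewer than 3 pairs retained for the disease regression",
         call. = FALSE)
  y <- log(d[keep] / s[keep])
  fit <- summary(stats::lm(y ~ x[keep]))
  list(slope = fit$coefficients[2, 1],
       slope_se = fit$coefficients[2, 2],
       intercept = fit$coefficients[1, 1],
       r_squared = fit$r.squared,
       p_value = fit$coefficients[2, 4],
       n = sum(keep))
}
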