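#' @title Synthetic-data generators
#'
#' @description
#' Generators with the statistical structure the analysis assumes: site-level
#' ddG scans scattered around a ground-truth matrix (with a per-site context
#' offset shared across the 19 destinations), rates drawn from the
#' partitioned Arrhenius model with lognormal noise, and Poisson
#' disease/polymorphism counts whose log ratio is linear in ddG. Each stage
#' of the pipeline can thereby be tested by parameter recovery, with no
#' external data. All generators are reproducible under a fixed seed.
#'
#' @name synthetic_data
NULL

#' Generate a synthetic site-scan table around a ground-truth matrix
#'
#' For each of `n_sites` sites, a wild-type residue is drawn (uniformly by
#' default, or from `wt_freqs`), and a ddG value is emitted for each of the
#' 19 destinations: truth(wt, dest) plus i.i.d. Gaussian noise of sd
#' `noise_sd` plus a Gaussian per-site offset of sd `site_sd` shared by the
#' 19 destinations of that site (the site-context component that median
#' aggregation must average away). Sites are grouped into proteins of 500
#' sites for bookkeeping.
#'
#' @param truth 20 x 20 ground-truth ddG matrix, complete off-diagonal.
#' @param n_sites Number of sites to simulate.
#' @param noise_sd Per-measurement noise sd (kcal/mol).
#' @param site_sd Per-site shared offset sd (kcal/mol, default 0).
#' @param wt_freqs Optional length-20 wild-type draw frequencies in
#'   canonical residue order (e.g. LG stationary frequencies).
#' @param seed Integer seed.
#' @return Site-scan data frame with `n_sites * 19` rows.
#' @export
generate_site_scans <- function(truth, n_sites, noise_sd = 0.5, site_sd = 0,
                                wt_freqs = NULL, seed = 1) {
  off <- truth[row(truth) != col(truth)]
  if (any(!is.finite(off)))
    stop("truth matrix must be complete off-diagonal", call. = FALSE)
  aa <- aa_residues()
  set.seed(seed)
  wt <- sample(aa, n_sites, replace = TRUE, prob = wt_freqs)
  offset <- stats::rnorm(n_sites, 0, site_sd)
  dest <- vapply(wt, function(w) aa[aa != w], character(19))  # 19 x n_sites
  wt_rep <- rep(wt, each = 19)
  mut <- as.vector(dest)
  ddg <- truth[cbind(match(wt_rep, aa), match(mut, aa))] +
    rep(offset, each = 19) +
    stats::rnorm(n_sites * 19, 0, noise_sd)
  data.frame(protein = sprintf("synth%05d", (rep(seq_len(n_sites), each = 19) - 1L) %/% 500L + 1L),
             position = rep(((seq_len(n_sites) - 1L) %% 500L) + 1L, each = 19),
             wt = wt_rep, mut = mut, ddg = ddg,
             stringsAsFactors = FALSE)
}

#' Generate rates from the partitioned Arrhenius model
#'
#' q(pair) = a_group * exp(-E/b) * exp(N(0, log_noise_sd)).
#'
#' @param E Non-negative barriers (380-vector).
#' @param assignment Group index per pair.
#' @param params [arrhenius_params()].
#' @param log_noise_sd Lognormal noise sd on the log scale.
#' @param seed Integer seed.
#' @return Vector of positive rates.
#' @export
generate_arrhenius_rates <- function(E, assignment,
                                     params = arrhenius_params(),
                                     log_noise_sd = 0.1, seed = 1) {
  base <- predict_rates(E, assignment, params)
  set.seed(seed)
  base * exp(stats::rnorm(length(base), 0, log_noise_sd))
}

#' Generate Poisson disease (DAR) and polymorphism (SAAP) counts
#'
#' saap(i,j) ~ Poisson(baseline) and dar(i,j) ~ Poisson(baseline *
#' exp(beta * ddg(i,j))), so the expected log ratio log(dar/saap) is
#' beta * ddg.
#'
#' @param ddg 20 x 20 ddG matrix, complete off-diagonal.
#' @param baseline Expected SAAP count per pair.
#' @param beta Slope of the log disease-causing potential in ddG.
#' @param seed Integer seed.
#' @return List of two 20 x 20 integer matrices, `dar` and `saap`.
#' @export
generate_disease_counts <- function(ddg, baseline = 1000, beta = 0.5,
                                    seed = 1) {
  x <- offdiagonal_vector(ddg)
  if (any(!is.finite(x)))
    stop("ddg matrix must be complete off-diagonal", call. = FALSE)
  set.seed(seed)
  saap <- stats::rpois(380, baseline)
  dar <- stats::rpois(380, baseline * exp(beta * x))
  list(dar = vector_to_matrix(dar), saap = vector_to_matrix(saap))
}
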