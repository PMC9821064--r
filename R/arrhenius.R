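#' @title Arrhenius model of amino-acid substitution rates
#'
#' @description
#' The model writes the instantaneous substitution rate of an ordered pair
#' as q_ij = a_ij * exp(-E_ij / b): an exponential fitness term driven by
#' the stability barrier E = |ddG| (kcal/mol), scaled by the dimensionless
#' evolutionary temperature b = 1, times a pre-exponential factor a that
#' absorbs everything acting at the mutation level. A single shared a
#' explains only a small part of the rate variance; letting a take one of
#' five fixed levels (0.01, 0.05, 0.1, 0.2, 0.4), with each pair assigned to
#' the nearest of the five Arrhenius curves, captures most of it.
#'
#' @name arrhenius_model
NULL

#' Arrhenius model parameters
#'
#' @param a_levels Strictly increasing positive pre-exponential levels.
#' @param b Evolutionary temperature (dimensionless scale for kcal/mol
#'   barriers).
#' @return List with class `arrhenius_params`.
#' @export
arrhenius_params <- function(a_levels = c(0.01, 0.05, 0.1, 0.2, 0.4), b = 1) {
  stopifnot(all(a_levels > 0), all(diff(a_levels) > 0), b > 0)
  structure(list(a_levels = a_levels, b = b), class = "arrhenius_params")
}

#' Single-factor Arrhenius fit
#'
#' Fits the linearized model ln(q) = ln(a) - E/b by OLS: the slope estimates
#' -1/b and exp(intercept) estimates the single shared pre-exponential
#' factor.
#'
#' @param E Non-negative energy barriers (380-vector).
#' @param q Positive empirical rates, same order.
#' @return List with `a_hat`, `slope`, `r_squared` and `p_value`.
#' @export
single_factor_fit <- function(E, q) {
  stopifnot(length(E) == length(q))
  if (any(q <= 0))
    stop("all rates must be positive (log undefined)", call. = FALSE)
  if (any(E < 0))
    stop("energy barriers must be non-negative", call. = FALSE)
  if (stats::var(log(q)) < 1e-24) {     # constant rates: nothing to explain
    return(list(a_hat = q[1], slope = 0, r_squared = 0, p_value = 1))
  }
  fit <- summary(stats::lm(log(q) ~ E))
  list(a_hat = exp(fit$coefficients[1, 1]),
       slope = fit$coefficients[2, 1],
       r_squared = fit$r.squared,
       p_value = fit$coefficients[2, 4])
}

#' Assign each substitution pair to the nearest Arrhenius curve
#'
#' Each observed point (E, q) is assigned to the level a_k whose curve
#' a_k * exp(-E/b) is closest. The default metric is the vertical distance
#' in linear rate space, |q - a_k exp(-E/b)|, which reproduces the published
#' partition; the log-space alternative |ln q - (ln a_k - E/b)| is
#' available. Ties go to the smaller level (reported via a message).
#'
#' @param E Non-negative barriers.
#' @param q Positive rates.
#' @param params [arrhenius_params()].
#' @param metric `"linear_vertical"` (default) or `"log_vertical"`.
#' @return Integer vector of group indices (1 = smallest a), with the pair
#'   names of `E` if present.
#' @export
assign_arrhenius_groups <- function(E, q, params = arrhenius_params(),
                                    metric = c("linear_vertical",
                                               "log_vertical")) {
  metric <- match.arg(metric)
  stopifnot(length(E) == length(q), length(E) >= 1L)
  if (any(q <= 0)) stop("rates must be positive", call. = FALSE)
  a <- params$a_levels
  # distances: rows = observations, columns = curves
  curve_logq <- outer(-E / params$b, log(a), "+")
  d <- if (metric == "log_vertical") {
    abs(log(q) - curve_logq)
  } else {
    abs(q - exp(curve_logq))
  }
  ties <- apply(d, 1, function(r) sum(r == min(r)) > 1L)
  if (any(ties))
    message(sum(ties), " tie(s) in curve assignment resolved toward the smaller level")
  g <- apply(d, 1, which.min)   # which.min takes the first (smaller a) on ties
  names(g) <- names(E)
  g
}

#' Predict substitution rates from the partitioned Arrhenius model
#'
#' @param E Non-negative barriers.
#' @param assignment Group indices from [assign_arrhenius_groups()].
#' @param params [arrhenius_params()].
#' @return Vector of predicted rates a_group * exp(-E/b).
#' @export
predict_rates <- function(E, assignment, params = arrhenius_params()) {
  if (length(assignment) != length(E) || anyNA(assignment))
    stop("assignment must cover every pair", call. = FALSE)
  params$a_levels[assignment] * exp(-E / params$b)
}

#' Compare predicted and empirical rate vectors
#'
#' @param q_hat Predicted rates (independent variable).
#' @param q_emp Empirical rates, same canonical order.
#' @return List with `pearson_r`, `r_squared` (OLS of `q_emp` on `q_hat`,
#'   equal to `pearson_r^2`), and `n`.
#' @export
compare_matrices <- function(q_hat, q_emp) {
  stopifnot(length(q_hat) == length(q_emp))
  if (stats::sd(q_hat) == 0 || stats::sd(q_emp) == 0)
    stop("zero variance in a rate vector", call. = FALSE)
  r <- stats::cor(q_hat, q_emp)
  list(pearson_r = r, r_squared = r^2, n = length(q_hat))
}

#' Pairwise Pearson correlations between rate vectors
#'
#' @param matrices Named list of equal-length rate vectors in the same
#'   canonical pair order.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_table <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  n <- lengths(matrices)
  if (length(unique(n)) != 1L)
    stop("rate vectors have mismatched lengths", call. = FALSE)
  nms <- Filter(Negate(is.null), lapply(matrices, names))
  if (length(nms) > 1 &&
      !all(vapply(nms, identical, logical(1), y = nms[[1]])))
    stop("rate vectors have mismatched pair orderings", call. = FALSE)
  stats::cor(do.call(cbind, matrices))
}
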