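test_that("single-factor fit recovers an exact exponential", {
  set.seed(2)
  E <- stats::runif(380, 0, 5)
  q <- 0.1 * exp(-E)
  fit <- single_factor_fit(E, q)
  expect_equal(fit$a_hat, 0.1)
  expect_equal(fit$slope, -1)
  expect_equal(fit$r_squared, 1)

  flat <- single_factor_fit(E, rep(0.2, 380))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(single_factor_fit(E, q - 0.1), "positive")
  expect_error(single_factor_fit(E - 10, q), "non-negative")
})

test_that("on-curve points are assigned to their own curve", {
  params <- arrhenius_params()
  expect_equal(unname(assign_arrhenius_groups(0, 0.4, params)), 5L)
  expect_equal(unname(assign_arrhenius_groups(2, 0.05 * exp(-2), params)), 2L)
  # every level, several barriers, both metrics
  for (metric in c("linear_vertical", "log_vertical")) {
    for (g in 1:5) {
      E <- c(0, 0.5, 1, 3)
      q <- params$a_levels[g] * exp(-E)
      expect_equal(unname(assign_arrhenius_groups(E, q, params, metric)),
                   rep(g, 4L), info = paste(metric, g))
    }
  }
})

test_that("assignment equals an independently coded brute-force argmin", {
  params <- arrhenius_params(a_levels = c(0.02, 0.07, 0.33), b = 1.4)
  set.seed(5)
  E <- stats::runif(200, 0, 6)
  q <- exp(stats::runif(200, log(1e-4), log(0.5)))
  for (metric in c("linear_vertical", "log_vertical")) {
    got <- assign_arrhenius_groups(E, q, params, metric)
    oracle <- vapply(seq_along(E), function(k) {
      d <- vapply(params$a_levels, function(a) {
        curve <- a * exp(-E[k] / params$b)
        if (metric == "log_vertical") abs(log(q[k]) - log(curve))
        else abs(q[k] - curve)
      }, numeric(1))
      which.min(d)
    }, integer(1))
    expect_equal(unname(got), oracle, info = metric)
  }
})

test_that("ties in assignment go to the smaller level", {
  # binary-exact midpoint between the two curves at E = 0
  params <- arrhenius_params(a_levels = c(0.25, 0.75))
  expect_message(
    g <- assign_arrhenius_groups(0, 0.5, params, "linear_vertical"),
    "tie")
  expect_equal(unname(g), 1L)
})

test_that("predicted rates follow a * exp(-E/b) and its bounds", {
  params <- arrhenius_params()
  expect_equal(predict_rates(0, 5L, params), 0.4)
  expect_equal(predict_rates(1, 4L, params), 0.2 * exp(-1))
  expect_equal(predict_rates(5.31, 5L, params), 0.4 * exp(-5.31))
  expect_equal(0.4 * exp(-5.31), 0.00197, tolerance = 2e-3)
  expect_error(predict_rates(c(0, 1), c(1L, NA), params), "cover")

  set.seed(8)
  E <- stats::runif(380, 0, 6)
  g <- sample(1:5, 380, replace = TRUE)
  qh <- predict_rates(E, g, params)
  expect_true(all(qh > 0 & qh <= max(params$a_levels)))
  # monotone decreasing in E within each group
  for (k in 1:5) {
    sel <- g == k
    o <- order(E[sel])
    expect_true(all(diff(qh[sel][o]) <= 0), info = k)
  }
})

test_that("comparison statistics are scale-invariant correlations", {
  set.seed(9)
  x <- stats::runif(380)
  cmp <- compare_matrices(x, x)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$n, 380L)
  y <- stats::runif(380)
  expect_equal(compare_matrices(x, 3.7 * y)$pearson_r,
               compare_matrices(x, y)$pearson_r)
  expect_equal(compare_matrices(x, y)$r_squared,
               compare_matrices(x, y)$pearson_r^2, tolerance = 1e-12)
  expect_error(compare_matrices(x, rep(1, 380)), "variance")
})

test_that("correlation tables are symmetric with unit diagonal", {
  qd <- offdiagonal_rates(empirical_rate_matrix("dayhoff"))
  ql <- offdiagonal_rates(empirical_rate_matrix("lg"))
  tab <- correlation_table(list(D = qd, L = ql))
  expect_equal(diag(tab), c(D = 1, L = 1))
  expect_equal(tab, t(tab))
  bad <- ql; names(bad) <- rev(names(bad))
  expect_error(correlation_table(list(D = qd, L = bad)), "ordering")
})

test_that("five-level model explains at least as much as the single factor", {
  ddg <- ddg_human_proteome()
  E <- pair_vector(energy_barrier(ddg))
  q <- offdiagonal_rates(empirical_rate_matrix("lg"))
  single <- single_factor_fit(E, q)
  q1 <- single$a_hat * exp(single$slope * E)
  groups <- assign_arrhenius_groups(E, q)
  q5 <- predict_rates(E, groups)
  expect_gte(compare_matrices(q5, q)$r_squared,
             compare_matrices(q1, q)$r_squared)
})

test_that("noise drives the model-recovery correlation toward 1", {
  ddg <- ddg_human_proteome()
  E <- pair_vector(energy_barrier(ddg))
  set.seed(4)
  groups <- sample(1:5, 380, replace = TRUE)
  q_hat <- predict_rates(E, groups)
  rs <- vapply(c(0.5, 0.2, 0.05), function(s) {
    q <- generate_arrhenius_rates(E, groups, log_noise_sd = s, seed = 10)
    compare_matrices(q_hat, q)$pearson_r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.99)
})
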