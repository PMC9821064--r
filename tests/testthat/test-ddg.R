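test_that("site scans are summarized by the per-pair median", {
  scans <- data.frame(protein = "p1", position = 1:3, wt = "A", mut = "R",
                      ddg = c(0.1, 0.2, 0.3))
  m <- summarize_site_scans(scans)
  expect_equal(m["A", "R"], 0.2)
  expect_equal(sum(is.finite(m)), 1L)   # unobserved pairs stay missing
  # row order cannot matter
  expect_identical(summarize_site_scans(scans[3:1, ]), m)
  expect_error(summarize_site_scans(scans[0, ]), "empty")
  scans$ddg[2] <- Inf
  expect_warning(m2 <- summarize_site_scans(scans), "non-finite")
  expect_equal(m2["A", "R"], 0.2)
})

test_that("site-scan i/o round-trips long and wide formats", {
  truth <- toy_ddg()
  scans <- generate_site_scans(truth, n_sites = 30, noise_sd = 0.1, seed = 3)
  long <- tempfile(fileext = ".tsv")
  write_site_scans(scans, long)
  expect_equal(read_site_scans(long), scans, ignore_attr = TRUE)

  # wide FoldX-like layout: one row per site, 19 destination columns
  wide <- tempfile(fileext = ".csv")
  sites <- unique(scans[, c("protein", "position", "wt")])
  wmat <- matrix(NA_real_, nrow(sites), 20,
                 dimnames = list(NULL, aa_residues()))
  for (k in seq_len(nrow(sites))) {
    sel <- scans$protein == sites$protein[k] &
      scans$position == sites$position[k]
    wmat[k, scans$mut[sel]] <- scans$ddg[sel]
  }
  utils::write.csv(cbind(sites, wmat), wide, row.names = FALSE)
  back <- read_site_scans(wide)
  m1 <- summarize_site_scans(scans)
  m2 <- summarize_site_scans(back)
  expect_equal(m1, m2)
})

test_that("bundled proteome matrix has the published entries and asymmetry", {
  ddg <- ddg_human_proteome()
  expect_equal(ddg["A", "R"], -0.12)
  expect_equal(ddg["G", "P"], 5.31)
  expect_equal(ddg["F", "P"], 4.59)
  expect_equal(ddg["P", "F"], 0.64)
  expect_gt(ddg["F", "P"], ddg["P", "F"])
  expect_equal(sum(is.finite(ddg)), 380L)
})

test_that("energy barrier is the absolute value and is idempotent", {
  ddg <- toy_ddg()
  e <- energy_barrier(ddg)
  expect_true(all(e[is.finite(e)] >= 0))
  expect_equal(e["A", "R"], abs(ddg["A", "R"]))
  expect_identical(energy_barrier(e), e)
  zero <- ddg; zero[] <- 0; diag(zero) <- NA
  expect_true(all(energy_barrier(zero) == 0, na.rm = TRUE))
  ddg["A", "R"] <- NA
  expect_error(energy_barrier(ddg), "missing")
})

test_that("rank association behaves on symmetric and relabelled matrices", {
  aa <- aa_residues()
  set.seed(11)
  half <- matrix(stats::runif(400), 20, 20)
  sym <- half + t(half)
  dimnames(sym) <- list(aa, aa)
  diag(sym) <- NA
  ra <- suppressMessages(rank_association(sym))
  expect_equal(ra$source_ranks, ra$destination_ranks)
  expect_equal(ra$r_squared, 1)
  expect_equal(ra$slope_sign, 1)

  # tie-free asymmetric matrix: rank statistics are label-invariant
  m <- matrix(stats::runif(400), 20, 20, dimnames = list(aa, aa))
  diag(m) <- NA
  perm <- sample(20)
  relabelled <- m[perm, perm]
  expect_equal(rank_association(relabelled)$r_squared,
               rank_association(m)$r_squared)
})

test_that("conservative/radical labels follow both criteria", {
  ddg <- ddg_human_proteome()
  labels <- classify_conservative_radical(ddg, energy_threshold = 1)
  expect_identical(labels["G>P", "energy_label"], "radical")
  expect_identical(nrow(labels), 380L)

  zero <- ddg; zero[] <- 0; diag(zero) <- NA
  expect_true(all(classify_conservative_radical(zero)$energy_label ==
                    "conservative"))
  expect_true(all(classify_conservative_radical(
    ddg, energy_threshold = Inf)$energy_label == "conservative"))

  # unchanged polarity and volume class => conservative under that criterion
  pv <- classify_conservative_radical(ddg)$pv_label
  pol <- default_polarity_classes(); vol <- default_volume_classes()
  pairs <- canonical_pairs()
  same <- pol[pairs$source] == pol[pairs$destination] &
    vol[pairs$source] == vol[pairs$destination]
  expect_true(all(pv[same] == "conservative"))
  expect_true(all(pv[!same] == "radical"))

  expect_error(classify_conservative_radical(
    ddg, polarity_classes = default_polarity_classes()[-1]), "cover")
})

test_that("disease regression excludes zero counts exactly like manual dropping", {
  ddg <- toy_ddg()
  counts <- generate_disease_counts(ddg, baseline = 500, beta = 0.4, seed = 7)
  fit <- suppressMessages(
    disease_potential_regression(ddg, counts$dar, counts$saap))
  expect_gt(fit$slope, 0)

  saap0 <- counts$saap
  saap0["A", "R"] <- 0
  fit0 <- suppressMessages(
    disease_potential_regression(ddg, counts$dar, saap0))
  # manual drop of that pair gives the same regression
  dar_m <- counts$dar; dar_m["A", "R"] <- 0   # excluded either way
  fit_m <- suppressMessages(
    disease_potential_regression(ddg, dar_m, saap0))
  expect_equal(fit0$slope, fit_m$slope)
  expect_equal(fit0$n, fit$n - 1L)

  few <- counts$saap; few[] <- 0; few["A", "R"] <- 5; few["A", "N"] <- 5
  expect_error(suppressMessages(
    disease_potential_regression(ddg, counts$dar, few)), "fewer than 3")
})
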