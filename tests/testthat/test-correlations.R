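test_that("Spearman correlation matches the rank-difference closed form", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  expect_equal(as.numeric(spearman_cor(x, y)), 1 - 6 * 4 / (5 * 24))
  expect_equal(as.numeric(spearman_cor(x, exp(x))), 1)
  expect_equal(as.numeric(spearman_cor(x, rev(x))), -1)
  expect_error(spearman_cor(c(1, 2), c(3, 4)), "3 complete pairs")
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("imputation leaves complete data untouched and respects donor support", {
  set.seed(3)
  tab <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  tab$b <- tab$a + rnorm(80, sd = 0.5)
  tab$c <- tab$a - tab$b + rnorm(80, sd = 0.5)
  pm <- list(b = c("a", "c"), c = c("a", "b"))
  # no missing cells: m identical copies
  out0 <- pmm_impute(tab, pm, m = 3, seed = 1)
  expect_length(out0, 3)
  expect_identical(out0[[1]], tab)
  # punch holes; observed cells must be preserved and imputed values must be
  # members of the observed support of their column
  tabm <- tab
  tabm$b[sample(80, 20)] <- NA
  tabm$c[sample(80, 15)] <- NA
  outs <- pmm_impute(tabm, pm, m = 4, maxit = 5, seed = 2)
  for (d in outs) {
    expect_false(anyNA(d))
    expect_identical(d$b[!is.na(tabm$b)], tabm$b[!is.na(tabm$b)])
    expect_true(all(d$b[is.na(tabm$b)] %in% tabm$b[!is.na(tabm$b)]))
    expect_true(all(d$c[is.na(tabm$c)] %in% tabm$c[!is.na(tabm$c)]))
  }
  # seeded determinism
  expect_identical(pmm_impute(tabm, pm, m = 2, seed = 9),
                   pmm_impute(tabm, pm, m = 2, seed = 9))
})

test_that("Rubin pooling follows the hand-computed combination rules", {
  # within variance 0.01 corresponds to n = 103; z-values 0.5 and 0.7
  rs <- tanh(c(0.5, 0.7))
  pooled <- pool_correlations(rs, n = 103)
  expect_equal(pooled$z, 0.6, tolerance = 1e-12)
  expect_equal(pooled$between, var(c(0.5, 0.7)), tolerance = 1e-12)
  expect_equal(pooled$se_z^2, 0.01 + 1.5 * 0.02, tolerance = 1e-12)
  expect_equal(pooled$r, tanh(0.6), tolerance = 1e-12)
  # all estimates equal: between-variance zero, pooled equals the estimate
  same <- pool_correlations(rep(0.4, 6), n = 100)
  expect_equal(same$r, 0.4)
  expect_equal(same$between, 0)
  # single imputation reduces to the plain Fisher interval
  one <- pool_correlations(0.3, n = 50)
  expect_equal(one$ci, tanh(atanh(0.3) + c(-1, 1) * qnorm(0.975) / sqrt(47)),
               tolerance = 1e-10)
  expect_error(pool_correlations(c(0.2, 1), 50), "Fisher")
})

test_that("comparing equal correlations in a symmetric structure gives z = 0", {
  aux <- c(r_ac = 0.3, r_ad = 0.2, r_bc = 0.2, r_bd = 0.3)
  res <- compare_dependent_correlations(0.45, 0.45, aux, n = 200)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
})

test_that("the covariance term matches an independent Dunn-Clark evaluation", {
  # independent oracle: the full asymptotic covariance formula coded
  # directly from the four-variable correlation matrix
  oracle_c <- function(R, rbar) {
    r_jh <- R[1, 3]; r_jm <- R[1, 4]; r_kh <- R[2, 3]; r_km <- R[2, 4]
    psi <- 0.5 * rbar^2 * (r_jh^2 + r_jm^2 + r_kh^2 + r_km^2) +
      r_jh * r_km + r_jm * r_kh -
      rbar * (r_jh * r_jm + r_kh * r_km + r_jh * r_kh + r_jm * r_km)
    psi / (1 - rbar^2)^2
  }
  set.seed(21)
  for (i in 1:5) {
    # random PSD correlation matrix of four variables
    A <- matrix(rnorm(16), 4)
    S <- crossprod(A) + diag(0.5, 4)
    R <- cov2cor(S)
    res <- compare_dependent_correlations(R[1, 2], R[3, 4], R, n = 500)
    rbar <- tanh((atanh(R[1, 2]) + atanh(R[3, 4])) / 2)
    expect_equal(res$c, oracle_c(R, rbar), tolerance = 1e-10)
  }
  # degenerate self-comparison: covariance term equals 1 so the statistic's
  # denominator vanishes, consistent with var(r) * n = (1 - r^2)^2
  Rd <- diag(4)
  r <- 0.6
  Rd[1, 2] <- Rd[2, 1] <- r
  Rd[3, 4] <- Rd[4, 3] <- r
  Rd[1, 3] <- Rd[3, 1] <- 1 - 1e-9
  Rd[2, 4] <- Rd[4, 2] <- 1 - 1e-9
  Rd[1, 4] <- Rd[4, 1] <- r
  Rd[2, 3] <- Rd[3, 2] <- r
  resd <- compare_dependent_correlations(r, r, Rd, n = 100)
  expect_equal(resd$c, 1, tolerance = 1e-6)
  expect_error(compare_dependent_correlations(0.9, -0.9,
                                              c(r_ac = 0.9, r_ad = 0.9,
                                                r_bc = 0.9, r_bd = 0.9), 100),
               "positive semidefinite")
})

test_that("stratified analysis with a single stratum matches the overall one", {
  cfg <- default_generator_config(400, seed = 15, missingness = FALSE)
  g <- generate_cohort(cfg)
  res <- stratified_correlations(g$cohort, labels = rep(1, nrow(g$cohort)),
                                 impute = FALSE)
  ov <- res$report[res$report$stratum == "overall", ]
  c1 <- res$report[res$report$stratum == "class_1", ]
  expect_equal(ov$r, c1$r, tolerance = 1e-12)
  expect_equal(nrow(ov), 5)
})

test_that("zero cross-trait coupling yields near-zero stratified correlations", {
  cfg <- default_generator_config(1500, seed = 16, missingness = FALSE)
  Psi <- cfg$factor_covariance
  Psi[1:2, 3:4] <- 0
  Psi[3:4, 1:2] <- 0
  cfg$factor_covariance <- Psi
  cfg$class_proportions <- 1
  cfg$class_growth_means <- cfg$class_growth_means[1]
  cfg$K <- 1L
  g <- generate_cohort(cfg)
  res <- stratified_correlations(g$cohort, impute = FALSE)
  expect_true(all(abs(res$report$r) < 0.08))
})
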