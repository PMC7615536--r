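design <- build_design(growth_spec())

test_that("single observed wave reduces to the univariate normal density", {
  p <- tiny_params()
  y <- rep(NA_real_, 13)
  y[3] <- 4.2
  S <- trajmix:::full_sigma(p, design)
  mu <- drop(design$Lambda %*% p$alpha[1, ])
  expect_equal(class_loglik(y, 1, p, design),
               dnorm(4.2, mu[3], sqrt(S[3, 3]), log = TRUE), tolerance = 1e-12)
})

test_that("fully observed and partially observed subjects match a dense oracle", {
  p <- tiny_params()
  cfg <- generator_config(15, c(0.7, 0.3),
                          list(p$alpha[1, ], p$alpha[2, ]),
                          factor_covariance = p$Psi,
                          residual_variances = p$theta,
                          missingness = list(prob = 0.25), seed = 42,
                          round_scores = FALSE)
  Y <- trajmix:::trait_matrix(generate_cohort(cfg)$cohort, design)
  S <- trajmix:::full_sigma(p, design)
  Mu <- design$Lambda %*% t(p$alpha)
  for (i in seq_len(nrow(Y))) {
    for (k in 1:2) {
      expect_equal(class_loglik(Y[i, ], k, p, design),
                   dense_mvn_loglik(Y[i, ], Mu[, k], S), tolerance = 1e-10)
    }
  }
})

test_that("FIML marginalisation equals numerical integration over a missing wave", {
  p <- tiny_params()
  S <- trajmix:::full_sigma(p, design)
  Mu <- design$Lambda %*% t(p$alpha)
  # two-wave toy: subject observed at A_7 and S_13 (correlated through Psi),
  # then S_13 dropped; the marginal density must equal the integral of the
  # bivariate density over the missing coordinate
  o2 <- c(2L, 11L)
  y2 <- c(3.1, 5.4)
  mu2 <- Mu[o2, 1]
  S2 <- S[o2, o2]
  joint <- function(t) {
    vapply(t, function(tt) {
      v <- c(y2[1], tt) - mu2
      exp(-0.5 * (2 * log(2 * pi) + log(det(S2)) +
                    drop(t(v) %*% solve(S2) %*% v)))
    }, 1)
  }
  marg_num <- log(integrate(joint, -Inf, Inf, rel.tol = 1e-10)$value)
  y <- rep(NA_real_, 13)
  y[o2[1]] <- y2[1]
  expect_equal(class_loglik(y, 1, p, design), marg_num, tolerance = 1e-6)
})

test_that("total mixture log-likelihood matches brute-force summation", {
  p <- tiny_params()
  cfg <- generator_config(20, c(0.7, 0.3), list(p$alpha[1, ], p$alpha[2, ]),
                          factor_covariance = p$Psi,
                          residual_variances = p$theta,
                          missingness = list(prob = 0.2), seed = 7,
                          round_scores = FALSE)
  Y <- trajmix:::trait_matrix(generate_cohort(cfg)$cohort, design)
  expect_equal(total_loglik(Y, p, design), dense_mixture_loglik(Y, p, design),
               tolerance = 1e-8)
})

test_that("K = 1 total log-likelihood is the sum of class log-likelihoods", {
  p1 <- model_params(1, tiny_params()$alpha[1, , drop = FALSE],
                     tiny_params()$Psi, tiny_params()$theta)
  cfg <- generator_config(10, 1, list(p1$alpha[1, ]),
                          factor_covariance = p1$Psi,
                          residual_variances = p1$theta, seed = 3)
  Y <- trajmix:::trait_matrix(generate_cohort(cfg)$cohort, design)
  direct <- sum(vapply(seq_len(nrow(Y)),
                       function(i) class_loglik(Y[i, ], 1, p1, design), 1))
  expect_equal(total_loglik(Y, p1, design), direct, tolerance = 1e-10)
})

test_that("duplicating every subject doubles the log-likelihood", {
  p <- tiny_params()
  cfg <- generator_config(8, c(0.7, 0.3), list(p$alpha[1, ], p$alpha[2, ]),
                          factor_covariance = p$Psi,
                          residual_variances = p$theta, seed = 9)
  Y <- trajmix:::trait_matrix(generate_cohort(cfg)$cohort, design)
  expect_equal(total_loglik(rbind(Y, Y), p, design),
               2 * total_loglik(Y, p, design), tolerance = 1e-10)
})

test_that("posterior probabilities follow the closed forms", {
  p <- tiny_params()
  cfg <- generator_config(12, c(0.7, 0.3), list(p$alpha[1, ], p$alpha[2, ]),
                          factor_covariance = p$Psi,
                          residual_variances = p$theta, seed = 5)
  Y <- trajmix:::trait_matrix(generate_cohort(cfg)$cohort, design)
  post <- e_step(Y, p, design)
  expect_equal(rowSums(post), rep(1, nrow(Y)), tolerance = 1e-10)
  # K = 1: all posteriors one
  p1 <- model_params(1, p$alpha[1, , drop = FALSE], p$Psi, p$theta)
  expect_true(all(e_step(Y, p1, design) == 1))
  # identical class parameters and equal weights: posteriors 1/K
  peq <- model_params(c(0.5, 0.5), rbind(p$alpha[1, ], p$alpha[1, ]),
                      p$Psi, p$theta)
  expect_equal(unname(e_step(Y, peq, design)),
               matrix(0.5, nrow(Y), 2), tolerance = 1e-12)
  # two-point closed form: log f = (-1, -3), equal priors
  expect_equal(1 / (1 + exp(-2)), 0.8807971, tolerance = 1e-6)
  lw <- c(-1, -3) + log(c(0.5, 0.5))
  expect_equal(exp(lw[1] - trajmix:::log_sum_exp(lw)), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
})

test_that("label permutation leaves the likelihood unchanged", {
  p <- tiny_params()
  cfg <- generator_config(15, c(0.7, 0.3), list(p$alpha[1, ], p$alpha[2, ]),
                          factor_covariance = p$Psi,
                          residual_variances = p$theta, seed = 11)
  Y <- trajmix:::trait_matrix(generate_cohort(cfg)$cohort, design)
  pswap <- model_params(p$pi[2:1], p$alpha[2:1, ], p$Psi, p$theta)
  expect_equal(total_loglik(Y, p, design), total_loglik(Y, pswap, design),
               tolerance = 1e-10)
})
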