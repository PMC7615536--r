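# shared fixtures and independent oracles

# independently coded dense multivariate-normal log-density (solve +
# determinant; the package path uses Cholesky back-substitution)
dense_mvn_loglik <- function(y, mu, Sigma) {
  o <- which(!is.na(y))
  yo <- y[o]
  So <- Sigma[o, o, drop = FALSE]
  mo <- mu[o]
  ld <- as.numeric(determinant(So, logarithm = TRUE)$modulus)
  qf <- drop(t(yo - mo) %*% solve(So) %*% (yo - mo))
  -0.5 * (length(o) * log(2 * pi) + ld + qf)
}

# brute-force mixture log-likelihood oracle
dense_mixture_loglik <- function(Y, params, design) {
  S <- trajmix:::full_sigma(params, design)
  Mu <- design$Lambda %*% t(params$alpha)
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    dens <- sum(vapply(seq_len(params$K), function(k) {
      params$pi[k] * exp(dense_mvn_loglik(Y[i, ], Mu[, k], S))
    }, 1))
    tot <- tot + log(dens)
  }
  tot
}

# small two-class parameter set used across likelihood/EM tests
tiny_params <- function() {
  alpha <- rbind(c(2, -0.05, -0.02, 3, -0.1, 0),
                 c(6, 0.2, 0.05, 9, 0.3, -0.1))
  Psi <- diag(c(0.5, 0.004, 0.8, 0.006))
  Psi[1, 3] <- Psi[3, 1] <- 0.3
  model_params(c(0.7, 0.3), alpha, Psi, theta = c(0.8, 1.5))
}

# best label permutation matching estimated to true class means
match_classes <- function(alpha_est, alpha_true) {
  K <- nrow(alpha_true)
  perms <- if (K == 2L) list(1:2, 2:1) else
    list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- perms[[1L]]
  bd <- Inf
  for (p in perms) {
    d <- sum((alpha_est[p, ] - alpha_true)^2)
    if (d < bd) {
      bd <- d
      best <- p
    }
  }
  best
}

# sharp one- and two-class scenarios derived from the recovery configuration
one_class_config <- function(n, seed) {
  cfg <- recovery_generator_config(n, seed)
  generator_config(n, 1, cfg$class_growth_means[1],
                   factor_covariance = cfg$factor_covariance,
                   residual_variances = cfg$residual_variances, seed = seed)
}

two_class_config <- function(n, seed) {
  cfg <- recovery_generator_config(n, seed)
  generator_config(n, c(0.7, 0.3), cfg$class_growth_means[c(1, 3)],
                   factor_covariance = cfg$factor_covariance,
                   residual_variances = cfg$residual_variances, seed = seed)
}

# minimal stand-in for a gmm_fit in tests that only need fit statistics
fake_fit <- function(K, loglik, n, psi_zero = FALSE) {
  list(K = K, loglik = loglik, n = n, n_parameters = n_parameters(K, psi_zero))
}
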