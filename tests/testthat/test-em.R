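design <- build_design(growth_spec())
spec <- growth_spec()

make_cohort <- function(n, seed, miss = 0.15, round_scores = FALSE) {
  p <- tiny_params()
  cfg <- generator_config(n, c(0.7, 0.3), list(p$alpha[1, ], p$alpha[2, ]),
                          factor_covariance = p$Psi,
                          residual_variances = p$theta,
                          missingness = if (miss > 0) list(prob = miss) else NULL,
                          seed = seed, round_scores = round_scores)
  generate_cohort(cfg)
}

test_that("symmetric posteriors with identical class starts keep classes equal", {
  g <- make_cohort(60, 21)
  Y <- trajmix:::trait_matrix(g$cohort, design)
  p <- tiny_params()
  psym <- model_params(c(0.5, 0.5), rbind(p$alpha[1, ], p$alpha[1, ]),
                       p$Psi, p$theta)
  post <- matrix(0.5, nrow(Y), 2)
  new <- m_step(Y, post, spec, psym, maxit = 5)
  expect_equal(new$alpha[1, ], new$alpha[2, ], tolerance = 1e-10)
  expect_equal(new$pi, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("hard-label M step solves the per-group weighted GLS equations", {
  g <- make_cohort(80, 22, miss = 0.2)
  Y <- trajmix:::trait_matrix(g$cohort, design)
  lab <- g$truth$labels
  post <- cbind(as.numeric(lab == 1), as.numeric(lab == 2))
  new <- m_step(Y, post, spec, tiny_params(), maxit = 400, tol = 1e-12)
  # at the inner optimum, alpha_k must satisfy the GLS normal equations for
  # group k under the returned covariance (independent closed form)
  S <- trajmix:::full_sigma(new, design)
  for (k in 1:2) {
    A <- matrix(0, 6, 6)
    b <- numeric(6)
    for (i in which(lab == k)) {
      o <- which(!is.na(Y[i, ]))
      Lo <- design$Lambda[o, , drop = FALSE]
      So <- solve(S[o, o, drop = FALSE])
      A <- A + t(Lo) %*% So %*% Lo
      b <- b + drop(t(Lo) %*% So %*% Y[i, o])
    }
    expect_equal(unname(drop(solve(A, b))), unname(new$alpha[k, ]),
                 tolerance = 1e-5)
  }
})

test_that("an M step from perturbed truth never decreases the likelihood", {
  for (s in 1:3) {
    g <- make_cohort(150, 30 + s)
    Y <- trajmix:::trait_matrix(g$cohort, design)
    p <- tiny_params()
    pert <- model_params(p$pi, p$alpha + matrix(rnorm(12, sd = 0.3), 2),
                         p$Psi, p$theta * 1.3)
    post <- e_step(Y, pert, design)
    new <- m_step(Y, post, spec, pert, maxit = 1)
    expect_gte(total_loglik(Y, new, design),
               total_loglik(Y, pert, design) - 1e-8)
  }
})

test_that("ECM iterations are monotone and the fit is a fixed point", {
  g <- make_cohort(250, 41, miss = 0.15)
  fit <- fit_gmm(g$cohort, 2, spec, n_starts = 6, n_final = 2, seed = 13)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-6 * (abs(tr[-1]) + 1)))
  expect_equal(fit$loglik, total_loglik(g$cohort, fit$params, design),
               tolerance = 1e-8)
  # restarting from the solution reproduces the log-likelihood
  Y <- trajmix:::trait_matrix(g$cohort, design)
  again <- trajmix:::run_em(Y, trajmix:::missing_patterns(Y), fit$params,
                            design, maxit = 50, tol = 1e-9)
  expect_equal(again$loglik, fit$loglik, tolerance = 1e-6 * abs(fit$loglik))
  # posterior rows sum to one
  expect_equal(rowSums(fit$posteriors), rep(1, fit$n), tolerance = 1e-10)
})

test_that("a one-class fit is deterministic in the start seed", {
  g <- make_cohort(120, 51)
  f1 <- fit_gmm(g$cohort, 1, spec, seed = 1)
  f2 <- fit_gmm(g$cohort, 1, spec, seed = 999)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9 * abs(f1$loglik))
  expect_equal(f1$params$alpha, f2$params$alpha, tolerance = 1e-6)
})

test_that("classes are reported largest first and recover a 2-class truth", {
  g <- make_cohort(800, 61, miss = 0.1, round_scores = TRUE)
  fit <- fit_gmm(g$cohort, 2, spec, n_starts = 8, n_final = 2, seed = 3)
  expect_true(all(diff(fit$params$pi) <= 0))
  perm <- match_classes(fit$params$alpha, g$truth$alpha)
  expect_lt(max(abs(fit$params$pi[perm] - g$truth$pi)), 0.03)
  expect_lt(max(abs(fit$params$alpha[perm, ] - g$truth$alpha)), 0.15)
})

test_that("no start beats an independent direct optimisation of the likelihood", {
  # small-n oracle: BFGS on an unconstrained reparameterisation of the same
  # likelihood, evaluated with the independently coded dense density
  for (s in 1:5) {
    g <- make_cohort(25, 70 + s, miss = 0)
    Y <- trajmix:::trait_matrix(g$cohort, design)
    truth <- g$truth$params
    unpack <- function(par) {
      alpha <- matrix(par[1:12], 2, byrow = TRUE)
      L <- matrix(0, 4, 4)
      L[lower.tri(L, diag = TRUE)] <- par[13:22]
      diag(L) <- exp(diag(L))
      Psi <- L %*% t(L)
      theta <- exp(par[23:24])
      pi1 <- plogis(par[25])
      structure(list(K = 2L, pi = c(pi1, 1 - pi1), alpha = alpha, Psi = Psi,
                     theta = theta), class = "model_params")
    }
    L0 <- t(chol(truth$Psi))
    diag(L0) <- log(diag(L0))
    start <- c(t(truth$alpha), L0[lower.tri(L0, diag = TRUE)],
               log(truth$theta), qlogis(truth$pi[1]))
    nll <- function(par) {
      p <- tryCatch(unpack(par), error = function(e) NULL)
      if (is.null(p)) return(1e10)
      v <- tryCatch(-dense_mixture_loglik(Y, p, design), error = function(e) 1e10)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- optim(start, nll, method = "BFGS",
                 control = list(maxit = 300, reltol = 1e-12))
    fit <- fit_gmm(Y, 2, spec, n_starts = 8, n_final = 3, seed = s,
                   tol = 1e-9, polish = TRUE)
    expect_gte(fit$loglik, -opt$value - 1e-4)
  }
})
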