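# ECM estimation of the parallel-process piecewise growth mixture.
#
# Latent data: class membership and the four free growth factors; missing
# waves are marginalised (FIML), never imputed.  One iteration = one E pass
# (posteriors + conditional factor moments, grouped by missingness pattern)
# followed by closed-form conditional maximisations of the expected
# complete-data log-likelihood in the order pi, free-factor means,
# second-slope means, Psi, theta.  Every step is an exact conditional
# maximiser, so the observed-data log-likelihood is non-decreasing.

em_pass <- function(Y, patterns, params, design, compute_update = TRUE,
                    fixed_post = NULL, theta_floor = 1e-4, psi_floor = 1e-6) {
  K <- params$K
  n <- nrow(Y)
  Lam <- design$Lambda
  Lf <- design$Lambda_free
  L2 <- Lam[, design$fixed, drop = FALSE]     # second-slope loadings, J x 2
  proc <- design$proc
  psi_zero <- isTRUE(design$spec$psi_zero)
  Psi <- params$Psi
  alpha <- params$alpha
  af <- alpha[, design$free, drop = FALSE]
  logpi <- log(params$pi)

  Sig <- full_sigma(params, design)
  Mu <- Lam %*% t(alpha)                      # J x K

  loglik <- 0
  post <- matrix(NA_real_, n, K)

  # accumulators (free-covariance branch)
  Sw <- numeric(K)
  Sm <- matrix(0, 4L, K)
  Smm <- array(0, c(4L, 4L, K))
  SV <- matrix(0, 4L, 4L)
  s2num <- matrix(0, 2L, K)
  s2den <- matrix(0, 2L, K)
  Sr2 <- numeric(2L)
  SVload <- numeric(2L)
  Nobs <- numeric(2L)

  for (g in patterns) {
    o <- g$obs
    q <- length(o)
    m <- length(g$rows)
    Yg <- Y[g$rows, o, drop = FALSE]
    R <- tryCatch(chol(Sig[o, o, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(R)) return(NULL)
    cst <- -0.5 * (q * log(2 * pi) + 2 * sum(log(diag(R))))
    llg <- matrix(0, m, K)
    for (k in seq_len(K)) {
      E <- t(Yg) - Mu[o, k]
      Z <- backsolve(R, E, transpose = TRUE)
      llg[, k] <- cst - 0.5 * colSums(Z * Z)
    }
    lw <- sweep(llg, 2L, logpi, `+`)
    lse <- row_log_sum_exp(lw)
    loglik <- loglik + sum(lse)
    pg <- exp(lw - lse)
    if (!is.null(fixed_post)) pg <- fixed_post[g$rows, , drop = FALSE]
    post[g$rows, ] <- pg

    if (!compute_update || psi_zero) next

    Lfo <- Lf[o, , drop = FALSE]
    {
      X <- backsolve(R, backsolve(R, Lfo, transpose = TRUE))   # Sig_oo^{-1} Lf_o
      XP <- X %*% Psi                                          # q x 4, equals t(B)
      V <- Psi - Psi %*% crossprod(Lfo, X) %*% Psi
      V <- (V + t(V)) / 2
      vload <- rowSums((Lfo %*% V) * Lfo)                      # lf_j' V lf_j per wave
      for (p in 1:2) {
        cp <- which(proc[o] == p)
        if (!length(cp)) next
        SVload[p] <- SVload[p] + m * sum(vload[cp])
        Nobs[p] <- Nobs[p] + m * length(cp)
      }
      SV <- SV + m * V
      for (k in seq_len(K)) {
        w <- pg[, k]
        sw <- sum(w)
        Ek <- sweep(Yg, 2L, Mu[o, k])                          # m x q
        Mk <- sweep(Ek %*% XP, 2L, af[k, ], `+`)               # m x 4 factor scores
        Sw[k] <- Sw[k] + sw
        Sm[, k] <- Sm[, k] + colSums(w * Mk)
        Smm[, , k] <- Smm[, , k] + crossprod(Mk, w * Mk)
        Rres <- Yg - Mk %*% t(Lfo)                             # y - lf' E[eta]
        for (p in 1:2) {
          cp <- which(proc[o] == p)
          if (!length(cp)) next
          l2 <- L2[o[cp], p]
          wR <- w * Rres[, cp, drop = FALSE]
          Sr2[p] <- Sr2[p] + sum(wR * Rres[, cp, drop = FALSE])
          if (any(l2 != 0)) {
            s2num[p, k] <- s2num[p, k] + sum(colSums(wR) * l2)
            s2den[p, k] <- s2den[p, k] + sw * sum(l2^2)
          }
        }
      }
    }
  }

  if (!compute_update) return(list(loglik = loglik, post = post, params_new = NULL))

  if (psi_zero) {
    return(em_update_lcga(Y, patterns, params, design, post, loglik,
                          theta_floor = theta_floor))
  }

  n_eff <- colSums(post)
  pi_new <- pmax(n_eff / n, 1e-10)
  pi_new <- pi_new / sum(pi_new)

  af_new <- af
  for (k in seq_len(K)) if (Sw[k] > 1e-8) af_new[k, ] <- Sm[, k] / Sw[k]

  s2_new <- t(alpha[, design$fixed, drop = FALSE])             # 2 x K, old values
  for (k in seq_len(K)) for (p in 1:2) {
    if (s2den[p, k] > 1e-10) s2_new[p, k] <- s2num[p, k] / s2den[p, k]
  }

  Psi_new <- SV
  for (k in seq_len(K)) {
    a <- af_new[k, ]
    Psi_new <- Psi_new + Smm[, , k] - tcrossprod(a, Sm[, k]) -
      tcrossprod(Sm[, k], a) + Sw[k] * tcrossprod(a)
  }
  Psi_new <- (Psi_new + t(Psi_new)) / (2 * n)
  diag(Psi_new) <- pmax(diag(Psi_new), psi_floor)

  theta_new <- params$theta
  for (p in 1:2) {
    if (Nobs[p] > 0) {
      ss <- Sr2[p] - 2 * sum(s2_new[p, ] * s2num[p, ]) +
        sum(s2_new[p, ]^2 * s2den[p, ]) + SVload[p]
      theta_new[p] <- max(ss / Nobs[p], theta_floor)
    }
  }

  alpha_new <- alpha
  alpha_new[, design$free] <- af_new
  alpha_new[, design$fixed] <- t(s2_new)

  params_new <- structure(list(K = K, pi = as.numeric(pi_new), alpha = alpha_new,
                               Psi = Psi_new, theta = theta_new),
                          class = "model_params")
  list(loglik = loglik, post = post, params_new = params_new)
}

# LCGA variant of the M step: Psi fixed at zero, per-class means by weighted
# GLS (diagonal covariance), residual variances from weighted squared
# residuals at the old means (theta first, then means: valid ECM order).
em_update_lcga <- function(Y, patterns, params, design, post, loglik,
                           theta_floor = 1e-4) {
  K <- params$K
  n <- nrow(Y)
  Lam <- design$Lambda
  proc <- design$proc
  Mu <- Lam %*% t(params$alpha)

  Sfull2 <- numeric(2L)
  Nobs <- numeric(2L)
  G1 <- array(0, c(6L, 6L, 2L, K))
  G2 <- array(0, c(6L, 2L, K))
  for (g in patterns) {
    o <- g$obs
    Yg <- Y[g$rows, o, drop = FALSE]
    m <- nrow(Yg)
    Lamo <- Lam[o, , drop = FALSE]
    for (p in 1:2) {
      cp <- which(proc[o] == p)
      if (!length(cp)) next
      Nobs[p] <- Nobs[p] + m * length(cp)
      Lp <- Lamo[cp, , drop = FALSE]
      cpr <- crossprod(Lp)
      for (k in seq_len(K)) {
        w <- post[g$rows, k]
        G1[, , p, k] <- G1[, , p, k] + sum(w) * cpr
        G2[, p, k] <- G2[, p, k] + drop(crossprod(Lp, crossprod(Yg[, cp, drop = FALSE], w)))
        Sfull2[p] <- Sfull2[p] + sum(w * sweep(Yg[, cp, drop = FALSE], 2L, Mu[o[cp], k])^2)
      }
    }
  }
  theta_new <- pmax(Sfull2 / pmax(Nobs, 1), theta_floor)
  alpha_new <- params$alpha
  for (k in seq_len(K)) {
    A <- G1[, , 1L, k] / theta_new[1L] + G1[, , 2L, k] / theta_new[2L]
    b <- G2[, 1L, k] / theta_new[1L] + G2[, 2L, k] / theta_new[2L]
    sol <- tryCatch(solve(A + diag(1e-8, 6L), b), error = function(e) NULL)
    if (!is.null(sol)) alpha_new[k, ] <- sol
  }
  pi_new <- pmax(colSums(post) / n, 1e-10)
  pi_new <- pi_new / sum(pi_new)
  params_new <- structure(list(K = K, pi = as.numeric(pi_new), alpha = alpha_new,
                               Psi = params$Psi, theta = theta_new),
                          class = "model_params")
  list(loglik = loglik, post = post, params_new = params_new)
}

#' One M step of the mixture ECM given fixed posteriors
#'
#' Maximises the expected complete-data log-likelihood over all model
#' parameters with the posterior class probabilities held fixed, by
#' iterating the closed-form conditional updates (free-factor means,
#' second-slope means, shared factor covariance, residual variances) to
#' convergence.  Satisfies the generalised-EM contract: the returned
#' parameters never decrease the observed-data log-likelihood when the
#' posteriors come from [e_step()] at `params`.
#'
#' @param data cohort table or waves matrix.
#' @param posteriors n x K matrix of class weights (rows sum to 1).
#' @param spec a [growth_spec()].
#' @param params current [model_params()] (starting point of the inner
#'   maximisation).
#' @param tol,maxit inner convergence control.
#' @return updated [model_params()].
#' @export
m_step <- function(data, posteriors, spec, params, tol = 1e-9, maxit = 200L) {
  design <- build_design(spec)
  Y <- trait_matrix(data, design)
  patterns <- missing_patterns(Y)
  if (any(abs(rowSums(posteriors) - 1) > 1e-8)) {
    stopf("posterior rows must sum to 1")
  }
  cur <- params
  last_q <- -Inf
  for (it in seq_len(maxit)) {
    res <- em_pass(Y, patterns, cur, design, fixed_post = posteriors)
    if (is.null(res)) stopf("inner maximisation failed (singular covariance)")
    # expected complete-data objective surrogate: weighted observed loglik
    q <- weighted_obs_loglik(Y, patterns, cur, design, posteriors)
    cur <- res$params_new
    if (is.finite(last_q) && abs(q - last_q) < tol * (abs(q) + 1)) break
    last_q <- q
  }
  cur
}

# sum_ik w_ik [log pi_k + log f_ik]; the mixture Q function given weights
weighted_obs_loglik <- function(Y, patterns, params, design, w) {
  ll <- pp_logdens(Y, params, design, patterns)
  sum(w * sweep(ll, 2L, log(params$pi), `+`))
}
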