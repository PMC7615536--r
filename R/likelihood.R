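# FIML likelihood of the parallel-process piecewise growth mixture.
#
# Per class k the observed score vector of a subject is multivariate normal
# with mean Lambda alpha_k and covariance Lambda_f Psi Lambda_f' + Theta,
# Theta diagonal with one residual variance per process.  Because Psi and
# theta are shared across classes the covariance matrix is class-invariant;
# only the mean differs.  Missing waves are marginalised by restricting mean
# and covariance to the observed rows (full-information ML).

# extract the waves matrix (n x J, NA = missing) from a cohort table
trait_matrix <- function(data, design) {
  if (is.matrix(data)) {
    if (ncol(data) != design$J) stopf("trait matrix must have %d columns", design$J)
    Y <- data
    colnames(Y) <- design$waves
    return(Y)
  }
  miss <- setdiff(design$waves, names(data))
  if (length(miss)) stopf("cohort is missing trait columns: %s", paste(miss, collapse = ", "))
  Y <- as.matrix(as.data.frame(data)[, design$waves])
  storage.mode(Y) <- "double"
  Y
}

# group subjects by missingness pattern; subjects must have >= 1 observed wave
missing_patterns <- function(Y) {
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0L)) stopf("every subject needs at least one observed wave")
  key <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  idx <- split(seq_len(nrow(Y)), key)
  lapply(idx, function(rows) list(rows = rows, obs = which(obs[rows[1L], ])))
}

# class-invariant covariance of the full wave vector
full_sigma <- function(params, design) {
  Lf <- design$Lambda_free
  S <- Lf %*% params$Psi %*% t(Lf)
  diag(S) <- diag(S) + params$theta[design$proc]
  S
}

# n x K matrix of per-class FIML log-densities
pp_logdens <- function(Y, params, design, patterns = NULL) {
  patterns <- patterns %||% missing_patterns(Y)
  K <- params$K
  Sig <- full_sigma(params, design)
  Mu <- design$Lambda %*% t(params$alpha)            # J x K class mean curves
  ll <- matrix(NA_real_, nrow(Y), K)
  for (g in patterns) {
    o <- g$obs
    q <- length(o)
    R <- tryCatch(chol(Sig[o, o, drop = FALSE]),
                  error = function(e) stopf("observed-wave covariance not positive definite"))
    logdet <- 2 * sum(log(diag(R)))
    Yg <- Y[g$rows, o, drop = FALSE]
    cst <- -0.5 * (q * log(2 * pi) + logdet)
    for (k in seq_len(K)) {
      E <- t(Yg) - Mu[o, k]
      Z <- backsolve(R, E, transpose = TRUE)
      ll[g$rows, k] <- cst - 0.5 * colSums(Z * Z)
    }
  }
  ll
}

#' Per-class log-likelihood of one subject's observed waves
#'
#' Log-density of a subject's observed score subvector under class `k`:
#' multivariate normal with mean \eqn{\Lambda \alpha_k} and covariance
#' \eqn{\Lambda_f \Psi \Lambda_f' + \Theta}, both restricted to the observed
#' rows (missing waves marginalised, full-information ML).
#'
#' @param y numeric vector of length `design$J` with `NA` for missing waves.
#' @param k class index.
#' @param params a [model_params()].
#' @param design a [build_design()] object.
#' @return scalar log-density.
#' @export
class_loglik <- function(y, k, params, design) {
  if (length(y) != design$J) stopf("`y` must have length %d", design$J)
  o <- which(!is.na(y))
  if (!length(o)) stopf("subject has no observed waves")
  Sig <- full_sigma(params, design)[o, o, drop = FALSE]
  mu <- drop(design$Lambda[o, , drop = FALSE] %*% params$alpha[k, ])
  R <- tryCatch(chol(Sig), error = function(e) stopf("observed-wave covariance not positive definite"))
  z <- backsolve(R, y[o] - mu, transpose = TRUE)
  -0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
}

#' Total mixture log-likelihood of a cohort
#'
#' Sum over subjects of the log mixture density
#' \eqn{\ln \sum_k \pi_k f_k(y_i)}, each subject contributing the marginal
#' density of its observed waves.
#'
#' @param data a cohort table (or n x J waves matrix with `NA` for missing).
#' @param params a [model_params()].
#' @param design a [build_design()] object.
#' @return scalar log-likelihood.
#' @export
total_loglik <- function(data, params, design) {
  Y <- trait_matrix(data, design)
  ll <- pp_logdens(Y, params, design)
  sum(row_log_sum_exp(sweep(ll, 2L, log(params$pi), `+`)))
}

#' Posterior class probabilities (E step)
#'
#' Computes \eqn{p_{ik} = \pi_k f_{ik} / \sum_j \pi_j f_{ij}} on the log
#' scale (log-sum-exp), so rows sum to one even when all class densities
#' underflow.
#'
#' @inheritParams total_loglik
#' @return n x K matrix of posterior probabilities.
#' @export
e_step <- function(data, params, design) {
  Y <- trait_matrix(data, design)
  lw <- sweep(pp_logdens(Y, params, design), 2L, log(params$pi), `+`)
  post <- exp(lw - row_log_sum_exp(lw))
  post / rowSums(post)
}
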