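# Class-enumeration statistics: information criteria, relative entropy,
# an adjusted likelihood-ratio test for k vs k-1 classes, and a parametric
# bootstrap LRT as the reference construction.

#' Information criteria for a fitted mixture
#'
#' `AIC = -2 LL + 2p`, `BIC = -2 LL + p ln n`.
#'
#' @param loglik maximised log-likelihood.
#' @param p number of free parameters (>= 1).
#' @param n number of subjects (>= 1).
#' @return named vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(loglik, p, n) {
  if (n < 1 || p < 1) stopf("need n >= 1 and p >= 1")
  c(AIC = -2 * loglik + 2 * p, BIC = -2 * loglik + p * log(n))
}

#' Relative entropy of a posterior classification
#'
#' `E = 1 - sum_i sum_k (-p_ik ln p_ik) / (n ln K)` with `0 ln 0 := 0`.
#' 1 means perfectly separated classes, 0 means uniformly uncertain
#' assignment.  Undefined for K = 1 (returns `NA` with a warning-free flag).
#'
#' @param posteriors n x K matrix with rows summing to 1.
#' @return scalar in `[0, 1]`, or `NA_real_` when K = 1.
#' @export
relative_entropy <- function(posteriors) {
  K <- ncol(posteriors)
  if (K < 2L) return(NA_real_)
  P <- pmin(pmax(posteriors, 0), 1)
  H <- -P * log(P)
  H[P == 0] <- 0
  1 - sum(H) / (nrow(posteriors) * log(K))
}

#' Adjusted likelihood-ratio test for k vs k-1 classes
#'
#' The package's analytic enumeration test: statistic
#' `2 (LL_k - LL_{k-1}) / c` with the small-sample correction
#' `c = 1 + 1 / ((p_k - p_{k-1}) ln n)`, referred to a chi-square whose
#' degrees of freedom are twice the number of extra non-mixing parameters
#' (the classical df convention for mixture likelihood-ratio tests, which
#' accounts for the boundary non-regularity of the mixing proportion).
#' Published implementations of the adjusted test differ in detail; the
#' parametric [bootstrap_lrt()] is the package's reference construction.
#'
#' @param fit_k,fit_km1 `gmm_fit` objects on the same data with
#'   `fit_k$K == fit_km1$K + 1`.
#' @return list with `statistic`, `df`, `p`, and the raw `lr`.
#' @export
lmr_test <- function(fit_k, fit_km1) {
  if (fit_k$K != fit_km1$K + 1L) stopf("fits must differ by exactly one class")
  if (fit_k$n != fit_km1$n) stopf("fits must be on identical data")
  lr <- 2 * (fit_k$loglik - fit_km1$loglik)
  if (lr < -1e-6 * (abs(fit_k$loglik) + 1)) {
    stopf("k-class log-likelihood below (k-1)-class value: non-converged fit")
  }
  lr <- max(lr, 0)
  d <- fit_k$n_parameters - fit_km1$n_parameters
  cc <- 1 + 1 / (d * log(fit_k$n))
  stat <- lr / cc
  df <- 2L * (d - 1L)        # extra parameters excluding the mixing proportion
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, lr = lr)
}

# simulate a cohort from fitted parameters, reusing an observed missingness
# mask (parametric bootstrap under the fitted continuous-normal model)
simulate_from_params <- function(params, design, n, mask = NULL, seed = 1L) {
  with_seed(seed, {
    labels <- sample.int(params$K, n, replace = TRUE, prob = params$pi)
    eta <- params$alpha[labels, , drop = FALSE]
    dev <- MASS::mvrnorm(n, mu = rep(0, 4L), Sigma = params$Psi)
    eta[, design$free] <- eta[, design$free] + rbind(dev)
    Y <- eta %*% t(design$Lambda)
    sds <- sqrt(params$theta)[design$proc]
    Y <- Y + matrix(stats::rnorm(n * design$J), n, design$J) * rep(sds, each = n)
    colnames(Y) <- design$waves
    if (!is.null(mask)) Y[mask] <- NA
    Y
  })
}

#' Parametric bootstrap likelihood-ratio test for k vs k-1 classes
#'
#' Fits k-1 and k classes to the data, simulates `B` datasets from the k-1
#' fit (reusing the observed missingness patterns), refits both models to
#' each, and returns `p = (1 + #\{LR_b >= LR_obs\}) / (B + 1)`.
#'
#' @param data cohort table or waves matrix.
#' @param k number of classes under the alternative (>= 2).
#' @param spec a [growth_spec()].
#' @param B number of bootstrap replicates (>= 19).
#' @param seed integer seed.
#' @param n_starts,n_final,tol fitting controls for the bootstrap refits
#'   (kept light by default).
#' @param fit_k,fit_km1 optional pre-computed fits on `data`.
#' @return list with `p`, `lr_obs`, vector `lr_boot`, and the two observed
#'   fits.
#' @export
bootstrap_lrt <- function(data, k, spec = growth_spec(), B = 49L, seed = 1L,
                          n_starts = 6L, n_final = 2L, tol = 1e-6,
                          fit_k = NULL, fit_km1 = NULL) {
  if (B < 19L) stopf("B must be >= 19")
  if (k < 2L) stopf("k must be >= 2")
  design <- build_design(spec)
  Y <- trait_matrix(data, design)
  fit_km1 <- fit_km1 %||% fit_gmm(Y, k - 1L, spec, n_starts = n_starts,
                                  n_final = n_final, seed = seed, tol = tol)
  fit_k <- fit_k %||% fit_gmm(Y, k, spec, n_starts = n_starts,
                              n_final = n_final, seed = seed, tol = tol)
  lr_obs <- max(2 * (fit_k$loglik - fit_km1$loglik), 0)
  mask <- is.na(Y)
  lr_boot <- rep(NA_real_, B)
  fails <- 0L
  b <- 0L
  attempt <- 0L
  while (b < B && fails < B) {
    attempt <- attempt + 1L
    Yb <- simulate_from_params(fit_km1$params, design, nrow(Y), mask = mask,
                               seed = child_seed(seed, 100L + attempt))
    f0 <- tryCatch(fit_gmm(Yb, k - 1L, spec, n_starts = max(2L, n_starts %/% 2L),
                           n_final = 1L, seed = child_seed(seed, 200L + attempt),
                           tol = tol),
                   error = function(e) NULL)
    f1 <- tryCatch(fit_gmm(Yb, k, spec, n_starts = n_starts, n_final = n_final,
                           seed = child_seed(seed, 300L + attempt), tol = tol),
                   error = function(e) NULL)
    if (is.null(f0) || is.null(f1)) {
      fails <- fails + 1L
      next
    }
    b <- b + 1L
    lr_boot[b] <- max(2 * (f1$loglik - f0$loglik), 0)
  }
  if (b < B) stopf("bootstrap fit failures exceeded the retry budget")
  p <- (1 + sum(lr_boot >= lr_obs)) / (B + 1)
  list(p = p, lr_obs = lr_obs, lr_boot = lr_boot, fit_k = fit_k,
       fit_km1 = fit_km1, B = B)
}

# one row of the enumeration table
model_fit_stats <- function(fit) {
  ic <- information_criteria(fit$loglik, fit$n_parameters, fit$n)
  data.frame(K = fit$K, loglik = fit$loglik, n_parameters = fit$n_parameters,
             AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]),
             entropy = relative_entropy(fit$posteriors),
             smallest_class_share = min(fit$params$pi),
             converged = fit$converged)
}

#' Enumerate the number of trajectory classes
#'
#' Fits k = 1..`k_max` class models, collects fit statistics (AIC, BIC,
#' relative entropy, smallest class share, adjusted LRT p-value per step)
#' and recommends the largest k whose adjusted-LRT p-value is below `alpha`
#' at every step up to k and whose smallest class share is at least
#' `min_class_share`.
#'
#' @param data cohort table or waves matrix.
#' @param k_max largest number of classes to consider (>= 2).
#' @param spec a [growth_spec()].
#' @param alpha LRT significance level for accepting an extra class.
#' @param min_class_share smallest admissible class share (default 5%).
#' @param seed integer seed for all fits.
#' @param n_starts,n_final,tol fitting controls passed to [fit_gmm()].
#' @return list with `stats` (one row per k; `lmr_p` is the p-value of the
#'   k vs k-1 test), `recommended_k`, and the list of `fits` (an error
#'   message string replaces a fit that failed; enumeration continues).
#' @export
enumerate_classes <- function(data, k_max, spec = growth_spec(), alpha = 0.05,
                              min_class_share = 0.05, seed = 1L,
                              n_starts = 20L, n_final = 5L, tol = 1e-7) {
  if (k_max < 2L) stopf("k_max must be >= 2")
  fits <- vector("list", k_max)
  rows <- list()
  for (k in seq_len(k_max)) {
    fits[[k]] <- tryCatch(
      fit_gmm(data, k, spec, n_starts = n_starts, n_final = n_final,
              seed = child_seed(seed, k), tol = tol),
      error = function(e) conditionMessage(e))
    if (inherits(fits[[k]], "gmm_fit")) {
      rows[[k]] <- model_fit_stats(fits[[k]])
    } else {
      rows[[k]] <- data.frame(K = k, loglik = NA_real_, n_parameters = NA,
                              AIC = NA_real_, BIC = NA_real_,
                              entropy = NA_real_,
                              smallest_class_share = NA_real_,
                              converged = FALSE)
    }
  }
  stats_df <- do.call(rbind, rows)
  stats_df$lmr_p <- NA_real_
  for (k in 2:k_max) {
    if (inherits(fits[[k]], "gmm_fit") && inherits(fits[[k - 1L]], "gmm_fit")) {
      stats_df$lmr_p[k] <- tryCatch(lmr_test(fits[[k]], fits[[k - 1L]])$p,
                                    error = function(e) NA_real_)
    }
  }
  recommended_k <- recommend_k(stats_df$lmr_p, stats_df$smallest_class_share,
                               alpha, min_class_share)
  list(stats = stats_df, recommended_k = recommended_k, fits = fits,
       rules = list(alpha = alpha, min_class_share = min_class_share))
}

#' Apply the class-enumeration decision rules
#'
#' Given per-k LRT p-values (`lmr_p[k]` tests k vs k-1; entry 1 is `NA`)
#' and smallest class shares, recommends the largest k whose LRT p-value is
#' below `alpha` at every step up to k and whose smallest class share meets
#' the minimum; defaults to 1.
#'
#' @param lmr_p,smallest_class_share vectors indexed by k = 1..k_max.
#' @param alpha significance level per enumeration step.
#' @param min_class_share smallest admissible class share.
#' @return recommended k.
#' @export
recommend_k <- function(lmr_p, smallest_class_share, alpha = 0.05,
                        min_class_share = 0.05) {
  k_max <- length(lmr_p)
  admissible <- rep(FALSE, k_max)
  admissible[1L] <- TRUE
  if (k_max >= 2L) for (k in 2:k_max) {
    steps_ok <- all(!is.na(lmr_p[2:k]) & lmr_p[2:k] < alpha)
    share_ok <- !is.na(smallest_class_share[k]) &&
      smallest_class_share[k] >= min_class_share
    admissible[k] <- steps_ok && share_ok
  }
  max(which(admissible))
}
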