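# Bias-corrected three-step association of latent trajectory classes with
# auxiliary covariates and distal outcomes.  Step 1: fit the mixture.
# Step 2: modal assignment and its classification-error matrix.  Step 3:
# covariate/outcome models that correct for the classification error
# (fixed-logit multinomial regression, BCH inverse-error weighting,
# posterior-weighted ML proportions).

#' Modal class assignment
#'
#' Argmax of each posterior row; ties broken by the lowest class index (the
#' number of ties is recorded in the `n_ties` attribute).
#'
#' @param posteriors n x K matrix, rows summing to 1.
#' @return integer labels `1..K`.
#' @export
modal_assignment <- function(posteriors) {
  lab <- max.col(posteriors, ties.method = "first")
  mx <- posteriors[cbind(seq_len(nrow(posteriors)), lab)]
  n_ties <- sum(rowSums(abs(posteriors - mx) < 1e-12) > 1L)
  structure(lab, n_ties = n_ties)
}

#' Classification-error matrix of a modal assignment
#'
#' `Q[j, k]` estimates the probability of modal assignment j given true
#' class k: the column-normalised average posterior among subjects assigned
#' j, `Q_jk = sum_{i: label_i = j} p_ik / sum_i p_ik`.  Columns sum to 1;
#' Q is the identity exactly when classification is perfect.
#'
#' @param posteriors n x K posterior matrix.
#' @param labels modal labels (defaults to [modal_assignment()]).
#' @return list with `Q` (K x K), assignment counts `N`, and the implied
#'   `entropy`.
#' @export
classification_error_matrix <- function(posteriors, labels = NULL) {
  labels <- labels %||% modal_assignment(posteriors)
  K <- ncol(posteriors)
  if (length(unique(labels)) < K) stopf("an assigned class is empty; classes too poorly separated")
  Q <- matrix(0, K, K)
  for (j in seq_len(K)) Q[j, ] <- colSums(posteriors[labels == j, , drop = FALSE])
  Q <- sweep(Q, 2L, colSums(posteriors), `/`)
  list(Q = Q, N = as.integer(table(factor(labels, levels = seq_len(K)))),
       entropy = relative_entropy(posteriors))
}

#' Bias-corrected three-step multinomial regression
#'
#' Regresses the *true* latent class on a covariate while treating the
#' modal assignment as an error-prone indicator with known error rates:
#' the assigned label `W` follows `P(W = j | x) = sum_k Q_jk P(C = k | x)`
#' with `P(C = k | x)` a multinomial logit (reference class 1) and the
#' measurement logits `ln Q_jk` held fixed.  With `Q = I` this is ordinary
#' multinomial regression on the labels.  Estimates are ML via BFGS;
#' standard errors come from the observed information.
#'
#' @param labels modal assignments `1..K`.
#' @param Q K x K classification-error matrix (columns sum to 1); zero
#'   entries are floored at 1e-6 before taking logs.
#' @param covariate numeric vector (binary 0/1 or continuous); missing
#'   values are listwise-deleted and the analysis n reported.
#' @return data frame with one row per class contrast (each class vs
#'   reference class 1 and all pairwise contrasts): log-odds, SE, OR, 95%
#'   Wald CI, p-value, analysis n.  Attribute `separation` flags unbounded
#'   estimates.
#' @export
threestep_multinomial <- function(labels, Q, covariate) {
  K <- ncol(Q)
  keep <- !is.na(covariate)
  w <- as.integer(labels)[keep]
  x <- as.numeric(covariate)[keep]
  n <- length(x)
  lQ <- log(pmax(Q, 1e-6))
  X <- cbind(1, x)
  # parameters: gamma_0k, gamma_1k for k = 2..K
  nll <- function(par) {
    G <- matrix(0, 2L, K)
    G[, -1L] <- matrix(par, 2L)
    lin <- X %*% G                           # n x K class logits
    lpc <- lin - row_log_sum_exp(lin)        # log P(C = k | x)
    # log P(W = w_i | x_i) = lse_k [ ln Q_{w_i, k} + lpc_ik ]
    m <- lQ[w, , drop = FALSE] + lpc
    -sum(row_log_sum_exp(m))
  }
  gr <- function(par) {
    G <- matrix(0, 2L, K)
    G[, -1L] <- matrix(par, 2L)
    lin <- X %*% G
    lpc <- lin - row_log_sum_exp(lin)
    m <- lQ[w, , drop = FALSE] + lpc
    r <- exp(m - row_log_sum_exp(m))         # responsibilities over true class
    D <- r - exp(lpc)
    -as.numeric(crossprod(X, D)[, -1L, drop = FALSE])
  }
  # start at the marginal assignment frequencies, zero covariate effect
  frq <- pmax(tabulate(w, K), 0.5) / length(w)
  start <- as.numeric(rbind(log(frq[-1L] / frq[1L]), 0))
  opt <- stats::optim(start, nll, gr, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500L, reltol = 1e-12))
  if (opt$value > nll(start) + 1e-8) {
    # fall back to a gradient-free search if line search ran off the surface
    opt <- stats::optim(start, nll, method = "Nelder-Mead", hessian = TRUE,
                        control = list(maxit = 2000L, reltol = 1e-12))
  }
  est <- opt$par
  V <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA_real_, length(est), length(est)))
  slope_idx <- seq(2L, 2L * (K - 1L), by = 2L)
  beta <- est[slope_idx]                     # covariate log-odds, class k vs 1
  vb <- V[slope_idx, slope_idx, drop = FALSE]
  sep <- any(abs(est) > 15)
  rows <- list()
  add_row <- function(cls, ref, b, se) {
    zcrit <- stats::qnorm(0.975)
    data.frame(class = cls, reference = ref, log_odds = b, se = se,
               OR = exp(b), ci_low = exp(b - zcrit * se),
               ci_high = exp(b + zcrit * se),
               p = 2 * stats::pnorm(-abs(b / se)), n = n)
  }
  for (k in 2:K) {
    rows[[length(rows) + 1L]] <- add_row(k, 1L, beta[k - 1L], sqrt(vb[k - 1L, k - 1L]))
  }
  if (K > 2L) {
    for (a in 2:(K - 1L)) for (b in (a + 1L):K) {
      d <- beta[b - 1L] - beta[a - 1L]
      se <- sqrt(vb[a - 1L, a - 1L] + vb[b - 1L, b - 1L] - 2 * vb[a - 1L, b - 1L])
      rows[[length(rows) + 1L]] <- add_row(b, a, d, se)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "separation") <- sep
  attr(out, "coefficients") <- est
  attr(out, "converged") <- opt$convergence == 0L
  out
}

#' BCH inverse-error weights
#'
#' Subject i with modal assignment j receives one weight per true class:
#' column j of `Q^{-1}` (equivalently row j of the inverse of the
#' true-class-conditional assignment matrix `t(Q)`).  Weights can be
#' negative; each subject's weights sum to 1 because the columns of Q do.
#'
#' @param labels modal assignments `1..K`.
#' @param Q K x K classification-error matrix.
#' @param max_condition condition-number threshold above which Q is treated
#'   as numerically singular (classes too poorly separated for BCH).
#' @return list with the n x K weight matrix `W`, `Qinv`, and the weighted
#'   class sizes `class_size = colSums(W)`.
#' @export
bch_weights <- function(labels, Q, max_condition = 1e8) {
  if (kappa(Q, exact = TRUE) > max_condition) {
    stopf("classification-error matrix is near-singular; classes too poorly separated for BCH")
  }
  Qinv <- solve(Q)
  W <- t(Qinv)[as.integer(labels), , drop = FALSE]
  list(W = W, Qinv = Qinv, class_size = colSums(W))
}

#' BCH distal-outcome means with Wald equality tests
#'
#' Class-specific means of a continuous distal outcome using BCH weights:
#' `mu_k = sum_i w_ik y_i / sum_i w_ik`, sandwich (estimating-equation)
#' standard errors and covariances, an overall Wald chi-square test of
#' equality across all classes (df = K-1) and pairwise tests (df = 1).
#'
#' @param weights result of [bch_weights()] (or an n x K weight matrix).
#' @param outcome numeric outcome; missing values listwise-deleted.
#' @return list with `means` data frame (class, mean, se, n), `wald`
#'   (statistic, df, p), `pairwise` data frame, and the mean covariance
#'   matrix `vcov`.
#' @export
bch_distal <- function(weights, outcome) {
  W <- if (is.list(weights)) weights$W else weights
  keep <- !is.na(outcome)
  W <- W[keep, , drop = FALSE]
  y <- as.numeric(outcome)[keep]
  K <- ncol(W)
  sw <- colSums(W)
  if (any(sw <= 0)) stopf("non-positive effective class size")
  mu <- colSums(W * y) / sw
  Vc <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in k:K) {
    Vc[k, l] <- Vc[l, k] <-
      sum(W[, k] * W[, l] * (y - mu[k]) * (y - mu[l])) / (sw[k] * sw[l])
  }
  D <- matrix(0, K - 1L, K)
  for (k in seq_len(K - 1L)) {
    D[k, k] <- 1
    D[k, K] <- -1
  }
  dmu <- D %*% mu
  DVD <- D %*% Vc %*% t(D)
  stat <- tryCatch(drop(t(dmu) %*% solve(DVD, dmu)), error = function(e) NA_real_)
  wald <- list(statistic = stat, df = K - 1L,
               p = stats::pchisq(stat, K - 1L, lower.tail = FALSE))
  pw <- list()
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    v <- Vc[a, a] + Vc[b, b] - 2 * Vc[a, b]
    s <- (mu[a] - mu[b])^2 / v
    pw[[length(pw) + 1L]] <- data.frame(
      class_a = a, class_b = b, diff = mu[a] - mu[b], se = sqrt(v),
      chisq = s, p = stats::pchisq(s, 1L, lower.tail = FALSE))
  }
  list(means = data.frame(class = seq_len(K), mean = mu, se = sqrt(diag(Vc)),
                          n = sum(keep), effective_n = sw),
       wald = wald, pairwise = do.call(rbind, pw), vcov = Vc)
}

#' Class-specific proportions of a binary distal outcome
#'
#' Posterior-weighted maximum likelihood with classification-error
#' adjustment: the outcome is modelled as Bernoulli within true class,
#' `P(y_i | traits_i) = sum_k p_ik rho_k^{y_i} (1 - rho_k)^{1 - y_i}`, and
#' the class-specific proportions `rho_k` are estimated by ML on the logit
#' scale.  Standard errors come from the observed information via the delta
#' method; pairwise class odds ratios with Wald CIs are derived from the
#' estimated logits.
#'
#' @param posteriors n x K posterior matrix.
#' @param outcome binary 0/1 outcome; missing values listwise-deleted.
#' @return list with `proportions` data frame (class, proportion, se, n),
#'   `odds_ratios` data frame (pairwise), logit covariance `vcov_logit`,
#'   and `flag` (character, non-empty when estimates were degenerate).
#' @export
dcat_proportions <- function(posteriors, outcome) {
  keep <- !is.na(outcome)
  P <- posteriors[keep, , drop = FALSE]
  y <- as.numeric(outcome)[keep]
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  K <- ncol(P)
  n <- length(y)
  flag <- character(0)
  nll <- function(lg) {
    rho <- stats::plogis(lg)
    lik <- P %*% rho * y + P %*% (1 - rho) * (1 - y)
    -sum(log(pmax(lik, 1e-300)))
  }
  start <- stats::qlogis(pmin(pmax(rep(mean(y), K), 0.02), 0.98))
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500L, reltol = 1e-12))
  lg <- opt$par
  if (any(abs(lg) > stats::qlogis(0.999))) {
    flag <- c(flag, "proportion estimate at boundary; clamped")
    lg <- pmin(pmax(lg, stats::qlogis(1e-3)), stats::qlogis(0.999))
  }
  Vl <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA_real_, K, K))
  rho <- stats::plogis(lg)
  se <- sqrt(pmax(diag(Vl), 0)) * rho * (1 - rho)
  zc <- stats::qnorm(0.975)
  ors <- list()
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    d <- lg[b] - lg[a]
    sd_ <- sqrt(Vl[a, a] + Vl[b, b] - 2 * Vl[a, b])
    ors[[length(ors) + 1L]] <- data.frame(
      class_a = a, class_b = b, OR = exp(d),
      ci_low = exp(d - zc * sd_), ci_high = exp(d + zc * sd_),
      p = 2 * stats::pnorm(-abs(d / sd_)))
  }
  list(proportions = data.frame(class = seq_len(K), proportion = rho, se = se, n = n),
       odds_ratios = do.call(rbind, ors), vcov_logit = Vl, flag = flag)
}
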