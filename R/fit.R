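# Multi-start ECM fitting of the growth mixture model.

# posterior-weighted empirical-Bayes factor scores (n x 4), used to seed
# k-means starts
factor_scores <- function(Y, patterns, params, design) {
  K <- params$K
  Sig <- full_sigma(params, design)
  Lam <- design$Lambda
  Lf <- design$Lambda_free
  Mu <- Lam %*% t(params$alpha)
  af <- params$alpha[, design$free, drop = FALSE]
  logpi <- log(params$pi)
  FS <- matrix(0, nrow(Y), 4L)
  for (g in patterns) {
    o <- g$obs
    Yg <- Y[g$rows, o, drop = FALSE]
    R <- chol(Sig[o, o, drop = FALSE])
    XP <- backsolve(R, backsolve(R, Lf[o, , drop = FALSE], transpose = TRUE)) %*% params$Psi
    llg <- matrix(0, nrow(Yg), K)
    Ms <- vector("list", K)
    cst <- -0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(R))))
    for (k in seq_len(K)) {
      E <- t(Yg) - Mu[o, k]
      Z <- backsolve(R, E, transpose = TRUE)
      llg[, k] <- cst - 0.5 * colSums(Z * Z)
      Ms[[k]] <- sweep(sweep(Yg, 2L, Mu[o, k]) %*% XP, 2L, af[k, ], `+`)
    }
    lw <- sweep(llg, 2L, logpi, `+`)
    pg <- exp(lw - row_log_sum_exp(lw))
    acc <- matrix(0, nrow(Yg), 4L)
    for (k in seq_len(K)) acc <- acc + pg[, k] * Ms[[k]]
    FS[g$rows, ] <- acc
  }
  FS
}

# moment-based single-class starting values
init_one_class <- function(Y, design) {
  cm <- colMeans(Y, na.rm = TRUE)
  cm[!is.finite(cm)] <- 0
  Lam <- design$Lambda
  A <- crossprod(Lam) + diag(1e-8, ncol(Lam))
  alpha <- matrix(drop(solve(A, crossprod(Lam, cm))), 1L)
  cv <- apply(Y, 2L, stats::var, na.rm = TRUE)
  cv[!is.finite(cv) | cv <= 0] <- 1
  vbar <- vapply(1:2, function(p) mean(cv[design$proc == p]), 1)
  Psi <- diag(c(0.4 * vbar[1L], 0.01 * vbar[1L], 0.4 * vbar[2L], 0.01 * vbar[2L]))
  structure(list(K = 1L, pi = 1, alpha = alpha, Psi = Psi, theta = 0.5 * vbar),
            class = "model_params")
}

run_em <- function(Y, patterns, params, design, maxit, tol, trace = FALSE) {
  trace_ll <- if (trace) numeric(0) else NULL
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  cur <- params
  ll <- NA_real_
  while (it < maxit) {
    it <- it + 1L
    res <- em_pass(Y, patterns, cur, design)
    if (is.null(res)) return(NULL)
    ll <- res$loglik
    if (trace) trace_ll <- c(trace_ll, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      # report the parameters the likelihood was evaluated at, so that
      # loglik == total_loglik(params) exactly
      converged <- TRUE
      break
    }
    ll_old <- ll
    last_entering <- cur
    cur <- res$params_new
  }
  if (!converged && it > 0L) cur <- last_entering
  list(params = cur, loglik = ll, n_iterations = it, converged = converged,
       trace = trace_ll)
}

params_from_centers <- function(centers, shares, base, K, design) {
  pi0 <- pmax(shares, 0.03)
  pi0 <- pi0 / sum(pi0)
  alpha <- matrix(0, K, 6L)
  alpha[, design$free] <- centers
  alpha[, design$fixed] <- matrix(base$alpha[1L, design$fixed], K, 2L, byrow = TRUE)
  structure(list(K = K, pi = pi0, alpha = alpha, Psi = 0.7 * base$Psi,
                 theta = base$theta),
            class = "model_params")
}

# random start for K classes: k-means on single-class factor scores + jitter
init_k_class <- function(Y, FS, base, K, design, jitter = 0.3) {
  sds <- pmax(apply(FS, 2L, stats::sd), 1e-3)
  km <- tryCatch(stats::kmeans(FS, centers = K, nstart = 10L, iter.max = 20L),
                 error = function(e) NULL)
  if (is.null(km)) {
    centers <- FS[sample.int(nrow(FS), K), , drop = FALSE]
    shares <- rep(1 / K, K)
  } else {
    centers <- km$centers
    shares <- as.numeric(table(factor(km$cluster, levels = seq_len(K)))) / nrow(FS)
  }
  centers <- centers + matrix(stats::rnorm(4L * K, sd = jitter), K, 4L) *
    rep(sds, each = K)
  params_from_centers(centers, shares, base, K, design)
}

# random-subject start: class centers drawn from K subjects' factor scores.
# Diversifies the start pool beyond k-means partitions, which tend to split
# a dominant class rather than isolate small ones
init_random_subjects <- function(FS, base, K, design) {
  idx <- sample.int(nrow(FS), K)
  params_from_centers(FS[idx, , drop = FALSE], rep(1 / K, K), base, K, design)
}

# deterministic hierarchical (Ward) start: separates small, well-defined
# classes that k-means tends to absorb into a split of the majority
init_hierarchical <- function(FS, base, K, design, max_points = 1200L) {
  idx <- if (nrow(FS) > max_points) {
    sample.int(nrow(FS), max_points)
  } else seq_len(nrow(FS))
  cl <- tryCatch({
    hc <- stats::hclust(stats::dist(FS[idx, , drop = FALSE]), method = "ward.D2")
    stats::cutree(hc, K)
  }, error = function(e) NULL)
  if (is.null(cl)) return(NULL)
  centers <- rowsum(FS[idx, , drop = FALSE], cl) /
    as.numeric(table(factor(cl, levels = seq_len(K))))
  shares <- as.numeric(table(factor(cl, levels = seq_len(K)))) / length(idx)
  params_from_centers(centers, shares, base, K, design)
}

# quasi-Newton refinement of an ECM solution on an unconstrained
# reparameterisation (log-Cholesky covariance, log variances, log-ratio
# mixing).  Used for high-precision small-sample fits; returns the input
# parameters unchanged unless the likelihood improves.
polish_fit <- function(Y, patterns, params, design, maxit = 300L) {
  K <- params$K
  psi_zero <- isTRUE(design$spec$psi_zero)
  obj_ll <- function(p) {
    ll <- pp_logdens(Y, p, design, patterns)
    sum(row_log_sum_exp(sweep(ll, 2L, log(p$pi), `+`)))
  }
  pack <- function(p) {
    out <- as.numeric(t(p$alpha))
    if (!psi_zero) {
      L <- t(chol(p$Psi + diag(1e-10, 4L)))
      diag(L) <- log(diag(L))
      out <- c(out, L[lower.tri(L, diag = TRUE)])
    }
    out <- c(out, log(pmax(p$theta, 1e-8)))
    if (K > 1L) out <- c(out, log(p$pi[-1L] / p$pi[1L]))
    out
  }
  unpack <- function(v) {
    alpha <- matrix(v[seq_len(6L * K)], K, 6L, byrow = TRUE)
    i <- 6L * K
    if (!psi_zero) {
      L <- matrix(0, 4L, 4L)
      L[lower.tri(L, diag = TRUE)] <- v[i + 1:10]
      diag(L) <- exp(pmin(diag(L), 20))
      Psi <- L %*% t(L)
      i <- i + 10L
    } else {
      Psi <- params$Psi
    }
    theta <- exp(pmin(v[i + 1:2], 20))
    i <- i + 2L
    pi <- if (K > 1L) {
      w <- exp(c(0, pmin(v[i + seq_len(K - 1L)], 30)))
      w / sum(w)
    } else 1
    structure(list(K = K, pi = pi, alpha = alpha, Psi = Psi, theta = theta),
              class = "model_params")
  }
  nll <- function(v) {
    val <- tryCatch(-obj_ll(unpack(v)), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  opt <- tryCatch(
    stats::optim(pack(params), nll, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-13)),
    error = function(e) NULL)
  if (is.null(opt)) return(list(params = params, loglik = obj_ll(params)))
  cand <- unpack(opt$par)
  ll0 <- obj_ll(params)
  ll1 <- tryCatch(obj_ll(cand), error = function(e) -Inf)
  if (is.finite(ll1) && ll1 > ll0) list(params = cand, loglik = ll1)
  else list(params = params, loglik = ll0)
}

# reorder classes by descending mixing proportion (largest class first)
order_classes <- function(params, post = NULL) {
  ord <- order(params$pi, decreasing = TRUE)
  params$pi <- params$pi[ord]
  params$alpha <- params$alpha[ord, , drop = FALSE]
  if (!is.null(post)) post <- post[, ord, drop = FALSE]
  list(params = params, post = post)
}

#' Fit the parallel-process piecewise growth mixture model
#'
#' Estimates a K-class mixture by multi-start ECM.  `n_starts` seeded random
#' initialisations (k-means on single-class empirical-Bayes growth-factor
#' scores, jittered) are each run for `burnin` iterations; the `n_final`
#' best are carried to convergence and the highest final log-likelihood
#' wins, ties broken by lowest start index.  Classes in the returned fit are
#' ordered by descending mixing proportion.
#'
#' @param data cohort table (or n x J waves matrix, `NA` = missing).
#' @param K number of classes (>= 1).
#' @param spec a [growth_spec()].
#' @param n_starts number of random initialisations (K >= 2).
#' @param n_final number of starts carried to full convergence.
#' @param seed integer seed governing all start randomness.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum ECM iterations per start.
#' @param burnin ECM iterations per start before triage.
#' @param polish refine the winning solution by quasi-Newton ascent on an
#'   unconstrained reparameterisation (high-precision mode for small
#'   samples; default off).
#' @return an object of class `gmm_fit`: fitted [model_params()],
#'   `loglik`, posterior matrix, parameter count, convergence diagnostics
#'   and the start-value log-likelihood table.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 150, seed = 7,
#'   class_proportions = 1,
#'   class_growth_means = list(c(3, 0.1, -0.05, 5, 0.2, -0.1)))
#' cohort <- generate_cohort(cfg)$cohort
#' fit <- fit_gmm(cohort, K = 1, growth_spec())
#' fit$loglik
fit_gmm <- function(data, K, spec = growth_spec(), n_starts = 50L, n_final = 10L,
                    seed = 1L, tol = 1e-7, maxit = 2000L, burnin = 15L,
                    polish = FALSE) {
  if (K < 1L) stopf("K must be >= 1")
  if (n_final > n_starts) stopf("n_final must not exceed n_starts")
  design <- build_design(spec)
  Y <- trait_matrix(data, design)
  n <- nrow(Y)
  if (K > floor(n / 4)) stopf("K = %d is infeasible for n = %d subjects", K, n)
  patterns <- missing_patterns(Y)

  base <- run_em(Y, patterns, init_one_class(Y, design), design,
                 maxit = maxit, tol = tol)
  if (is.null(base)) stopf("single-class base fit failed")

  if (K == 1L) {
    fin <- run_em(Y, patterns, base$params, design, maxit = maxit, tol = tol,
                  trace = TRUE)
    if (polish) {
      pol <- polish_fit(Y, patterns, fin$params, design)
      fin$params <- pol$params
      fin$loglik <- pol$loglik
    }
    post <- matrix(1, n, 1L)
    return(new_gmm_fit(fin, post, K, n, spec, design,
                       start_logliks = data.frame(start = 1L,
                                                  burnin_loglik = fin$loglik,
                                                  final_loglik = fin$loglik),
                       best_start = 1L))
  }

  FS <- factor_scores(Y, patterns, base$params, design)
  burn <- vector("list", n_starts)
  burn_ll <- rep(-Inf, n_starts)
  for (s in seq_len(n_starts)) {
    st <- if (s == 1L) {
      with_seed(child_seed(seed, 0L),
                init_hierarchical(FS, base$params, K, design)) %||%
        with_seed(child_seed(seed, s), init_k_class(Y, FS, base$params, K, design))
    } else if (s %% 2L == 0L) {
      with_seed(child_seed(seed, s),
                init_random_subjects(FS, base$params, K, design))
    } else {
      with_seed(child_seed(seed, s), init_k_class(Y, FS, base$params, K, design))
    }
    r <- run_em(Y, patterns, st, design, maxit = burnin, tol = tol)
    if (!is.null(r) && is.finite(r$loglik)) {
      burn[[s]] <- r$params
      burn_ll[s] <- r$loglik
    }
  }
  if (all(!is.finite(burn_ll))) stopf("no start produced a usable likelihood")
  keep <- order(burn_ll, decreasing = TRUE)[seq_len(min(n_final, sum(is.finite(burn_ll))))]
  final_ll <- rep(NA_real_, n_starts)
  finals <- vector("list", n_starts)
  for (s in keep) {
    r <- run_em(Y, patterns, burn[[s]], design, maxit = maxit, tol = tol,
                trace = TRUE)
    if (!is.null(r) && is.finite(r$loglik)) {
      finals[[s]] <- r
      final_ll[s] <- r$loglik
    }
  }
  if (all(is.na(final_ll))) stopf("no start converged")
  # best final loglik; ties (within 1e-8) broken by lowest start index
  best <- which(final_ll >= max(final_ll, na.rm = TRUE) - 1e-8)[1L]
  fin <- finals[[best]]
  if (polish) {
    pol <- polish_fit(Y, patterns, fin$params, design)
    fin$params <- pol$params
    fin$loglik <- pol$loglik
  }
  ord <- order_classes(fin$params, e_step(Y, fin$params, design))
  fin$params <- ord$params
  new_gmm_fit(fin, ord$post, K, n, spec, design,
              start_logliks = data.frame(start = seq_len(n_starts),
                                         burnin_loglik = burn_ll,
                                         final_loglik = final_ll),
              best_start = best)
}

new_gmm_fit <- function(fin, post, K, n, spec, design, start_logliks, best_start) {
  structure(list(params = fin$params, loglik = fin$loglik, posteriors = post,
                 n_parameters = n_parameters(K, spec$psi_zero), K = K, n = n,
                 converged = fin$converged, n_iterations = fin$n_iterations,
                 loglik_trace = fin$trace, start_logliks = start_logliks,
                 best_start = best_start, spec = spec, design = design),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("parallel-process growth mixture fit: K = %d, n = %d\n", x$K, x$n))
  cat(sprintf("log-likelihood %.3f (%d parameters), %sconverged in %d iterations\n",
              x$loglik, x$n_parameters, if (x$converged) "" else "NOT ", x$n_iterations))
  cat("class shares:", paste(sprintf("%.3f", x$params$pi), collapse = " "), "\n")
  invisible(x)
}
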