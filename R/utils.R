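# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# rowwise log-sum-exp of a matrix
row_log_sum_exp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

# round half away from zero (score totals; base round() is round-half-even)
round_half_up <- function(x) {
  floor(abs(x) + 0.5) * sign(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_prob_vector <- function(p, what = "probabilities", tol = 1e-12) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1 + tol)) {
    stopf("%s must lie in (0, 1)", what)
  }
  if (abs(sum(p) - 1) > tol) {
    stopf("%s must sum to 1 (got %.15f)", what, sum(p))
  }
  invisible(p)
}

check_psd <- function(M, what = "matrix", tol = -1e-10) {
  if (!isSymmetric(unname(M), tol = 1e-8)) stopf("%s must be symmetric", what)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < tol * max(1, abs(max(ev)))) {
    stopf("%s has a negative eigenvalue (%.3e)", what, min(ev))
  }
  invisible(M)
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# derive a bounded child seed from (seed, index) for independent sub-streams
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483587) + 1L
}
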