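#' Define the piecewise parallel-process growth model
#'
#' A `growth_spec` fixes the measurement design of the two-process piecewise
#' growth mixture model: the ages at which each trait process is measured,
#' the knot age at which the two linear growth segments join, and the
#' identification constraints used throughout the package (second-slope
#' variances fixed to zero, time-invariant residual variance per process,
#' growth-factor covariance shared across classes).
#'
#' Each process has a single intercept (centred at the process's first
#' measurement age), one linear slope for ages up to the knot and a second
#' linear slope for ages past the knot.  With only two post-knot waves per
#' process the second-slope variance is not identified and is fixed to zero,
#' so the free (random) growth factors are the two intercepts and the two
#' first slopes.
#'
#' @param ages named list of strictly increasing measurement ages (in years)
#'   for the two processes, default the ADHD-trait (`A`) and
#'   social-communication (`S`) designs: 4,7,8,9,12,13,17,25 and
#'   7,10,13,17,25.
#' @param knot age (years) at which the two linear segments join; default 17.
#' @param ranges named list of observed score ranges, default 0-10 for `A`
#'   and 0-24 for `S`.
#' @param psi_zero if `TRUE` the growth-factor covariance is fixed to zero
#'   (latent class growth analysis style) instead of freely estimated.
#' @param age_map optional named numeric vector mapping canonical integer age
#'   labels (as character, e.g. `"7"`) to the mean completion age actually
#'   used as the time metric.  Loadings are computed from the mapped ages;
#'   column labels keep the canonical ages.
#'
#' @return an object of class `growth_spec`.
#' @export
#' @examples
#' spec <- growth_spec()
#' build_design(spec)$Lambda
growth_spec <- function(ages = list(A = c(4, 7, 8, 9, 12, 13, 17, 25),
                                    S = c(7, 10, 13, 17, 25)),
                        knot = 17,
                        ranges = list(A = c(0, 10), S = c(0, 24)),
                        psi_zero = FALSE,
                        age_map = NULL) {
  if (!is.list(ages) || length(ages) != 2L || is.null(names(ages))) {
    stopf("`ages` must be a named list with one age vector per process")
  }
  for (p in names(ages)) {
    a <- ages[[p]]
    if (any(diff(a) <= 0)) stopf("ages for process %s must be strictly increasing", p)
    if (knot <= min(a) || knot > max(a)) stopf("knot must lie within the age range of process %s", p)
    if (sum(a <= knot) < 2L) stopf("process %s needs at least two ages at or before the knot", p)
    if (sum(a > knot) < 1L) stopf("process %s needs at least one age after the knot", p)
  }
  if (!is.null(age_map)) {
    if (is.null(names(age_map))) stopf("`age_map` must be a named numeric vector")
  }
  structure(
    list(ages = ages, knot = knot, ranges = ranges,
         psi_zero = isTRUE(psi_zero), age_map = age_map,
         processes = names(ages)),
    class = "growth_spec"
  )
}

# time metric for a vector of canonical ages
metric_age <- function(ages, age_map) {
  if (is.null(age_map)) return(ages)
  key <- as.character(ages)
  out <- ages
  hit <- key %in% names(age_map)
  out[hit] <- age_map[key[hit]]
  out
}

#' Build the factor-loading matrix of a piecewise growth spec
#'
#' Constructs the loading matrix \eqn{\Lambda} implied by a [growth_spec()]:
#' per process, an all-ones intercept column, a first-slope column
#' \eqn{\min(age, knot) - first\_age} and a second-slope column
#' \eqn{\max(age - knot, 0)}.
#'
#' @param spec a [growth_spec()].
#' @return an object of class `design_matrix`: a list with the combined
#'   loading matrix `Lambda` (waves x 6 growth factors, factor order
#'   `i_A, s1_A, s2_A, i_S, s1_S, s2_S`), the submatrix `Lambda_free` for the
#'   four free factors, the process index `proc` of each wave, wave column
#'   names `waves`, and per-process loading matrices.
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  procs <- spec$processes
  blocks <- list()
  for (p in procs) {
    a <- metric_age(spec$ages[[p]], spec$age_map)
    first <- a[1L]
    L <- cbind(intercept = rep(1, length(a)),
               slope1 = pmin(a, spec$knot) - first,
               slope2 = pmax(a - spec$knot, 0))
    rownames(L) <- paste(p, spec$ages[[p]], sep = "_")
    blocks[[p]] <- L
  }
  J <- sum(vapply(blocks, nrow, 1L))
  Lambda <- matrix(0, J, 3L * length(procs))
  proc <- integer(J)
  rn <- character(J)
  r0 <- 0L
  for (i in seq_along(procs)) {
    B <- blocks[[i]]
    rows <- r0 + seq_len(nrow(B))
    cols <- (i - 1L) * 3L + 1:3
    Lambda[rows, cols] <- B
    proc[rows] <- i
    rn[rows] <- rownames(B)
    r0 <- r0 + nrow(B)
  }
  fac <- as.vector(vapply(procs, function(p) paste(c("i", "s1", "s2"), p, sep = "_"),
                          character(3)))
  dimnames(Lambda) <- list(rn, fac)
  free <- which(!grepl("^s2", fac))
  structure(
    list(Lambda = Lambda, Lambda_free = Lambda[, free, drop = FALSE],
         free = free, fixed = setdiff(seq_along(fac), free),
         proc = proc, waves = rn, J = J, blocks = blocks, spec = spec),
    class = "design_matrix"
  )
}

#' Construct mixture model parameters
#'
#' Bundles the parameters of a K-class parallel-process piecewise growth
#' mixture: mixing proportions, per-class growth-factor means, the
#' growth-factor covariance of the four free factors (shared across classes)
#' and the two time-invariant residual variances.
#'
#' @param pi mixing proportions (length K, summing to 1).
#' @param alpha K x 6 matrix of growth-factor means, columns ordered
#'   `i_A, s1_A, s2_A, i_S, s1_S, s2_S`.
#' @param Psi 4 x 4 symmetric positive-semidefinite covariance of the free
#'   growth factors `(i_A, s1_A, i_S, s1_S)`, shared across classes.
#' @param theta length-2 vector of residual variances, one per process.
#' @return an object of class `model_params`.
#' @export
model_params <- function(pi, alpha, Psi, theta) {
  alpha <- rbind(alpha)
  K <- length(pi)
  check_prob_vector(pi, "mixing proportions")
  if (nrow(alpha) != K || ncol(alpha) != 6L) {
    stopf("`alpha` must be a %d x 6 matrix of growth-factor means", K)
  }
  if (!all(dim(Psi) == c(4L, 4L))) stopf("`Psi` must be 4 x 4 (free factors)")
  check_psd(Psi, "Psi")
  if (length(theta) != 2L || any(theta < 0)) stopf("residual variances must be >= 0")
  structure(list(K = K, pi = as.numeric(pi), alpha = unname(alpha),
                 Psi = unname(as.matrix(Psi)), theta = as.numeric(theta)),
            class = "model_params")
}

#' Number of free parameters of a fitted mixture
#'
#' Counts free parameters under the package's identification constraints:
#' 6 growth-factor means per class, K - 1 mixing proportions, 10 entries of
#' the shared free-factor covariance (0 when the spec fixes it to zero) and
#' 2 residual variances.
#'
#' @param K number of classes.
#' @param psi_zero whether the growth-factor covariance is fixed to zero.
#' @return integer parameter count.
#' @export
n_parameters <- function(K, psi_zero = FALSE) {
  6L * K + (K - 1L) + (if (psi_zero) 0L else 10L) + 2L
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("parallel-process growth mixture parameters: %d class(es)\n", x$K))
  cat("mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("growth-factor means (i_A, s1_A, s2_A, i_S, s1_S, s2_S):\n")
  print(round(x$alpha, 3))
  cat("residual variances (A, S):", paste(sprintf("%.3f", x$theta), collapse = " "), "\n")
  invisible(x)
}
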