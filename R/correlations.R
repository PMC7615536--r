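# Correlation workflow: Spearman rank correlations between the two trait
# series across ages, chained-equations predictive-mean-matching multiple
# imputation, Rubin-pooled estimates, comparison of dependent correlations
# (Silver's modification of Dunn & Clark's z), and class-stratified reports.

#' Spearman rank correlation of complete pairs
#'
#' Pearson correlation of average-ranked values (ties averaged), computed on
#' complete pairs.
#'
#' @param x,y paired numeric vectors.
#' @return `r_s` in `[-1, 1]`; attribute `n` gives the complete-pair count.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) stopf("need at least 3 complete pairs")
  rx <- rank(x[keep])
  ry <- rank(y[keep])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stopf("zero variance in ranks")
  structure(stats::cor(rx, ry), n = sum(keep))
}

# default predictor sets for chained imputation of the wave columns: a trait
# score is predicted from all other waves of its own trait, the other
# trait's score at the anchor age, and the other trait's scores at the
# paired and the previous timepoint
mi_predictor_map <- function(spec = growth_spec()) {
  design <- build_design(spec)
  pa <- spec$processes[1L]
  ps <- spec$processes[2L]
  a_ages <- spec$ages[[pa]]
  s_ages <- spec$ages[[ps]]
  a_cols <- design$waves[design$proc == 1L]
  s_cols <- design$waves[design$proc == 2L]
  nearest <- function(age, pool) pool[which.min(abs(pool - age))]
  map <- list()
  for (i in seq_along(a_ages)) {
    same <- nearest(a_ages[i], s_ages)
    prev <- s_ages[s_ages < same]
    others <- unique(c(s_ages[1L], if (length(prev)) max(prev), same))
    map[[a_cols[i]]] <- c(a_cols[-i], paste(ps, others, sep = "_"))
  }
  for (i in seq_along(s_ages)) {
    same <- nearest(s_ages[i], a_ages)
    prev <- a_ages[a_ages < same]
    others <- unique(c(a_ages[1L], if (length(prev)) max(prev), same))
    map[[s_cols[i]]] <- c(s_cols[-i], paste(pa, others, sep = "_"))
  }
  map
}

# one Bayesian linear-regression PMM update of a single column
pmm_update_column <- function(y, obs, X, donors, ridge = 1e-5) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  p <- ncol(Xo)
  S <- crossprod(Xo) + diag(ridge * max(1, mean(diag(crossprod(Xo)))), p)
  Sinv <- solve(S)
  beta_hat <- drop(Sinv %*% crossprod(Xo, yo))
  resid <- yo - drop(Xo %*% beta_hat)
  df <- max(length(yo) - p, 1L)
  sigma2 <- sum(resid^2) / stats::rchisq(1L, df)
  beta_star <- beta_hat + drop(crossprod(chol(sigma2 * Sinv), stats::rnorm(p)))
  pred_o <- drop(Xo %*% beta_hat)
  pred_m <- drop(X[!obs, , drop = FALSE] %*% beta_star)
  # donor search over a sorted window of predicted means
  ord <- order(pred_o)
  po <- pred_o[ord]
  yo_s <- yo[ord]
  n_o <- length(po)
  out <- numeric(length(pred_m))
  pos <- findInterval(pred_m, po)
  for (i in seq_along(pred_m)) {
    lo <- max(1L, pos[i] - donors)
    hi <- min(n_o, pos[i] + donors)
    cand <- lo:hi
    d <- abs(po[cand] - pred_m[i])
    pick <- cand[order(d)[seq_len(min(donors, length(cand)))]]
    out[i] <- yo_s[pick[sample.int(length(pick), 1L)]]
  }
  out
}

#' Multiple imputation by chained-equations predictive mean matching
#'
#' Each incomplete column is regressed on its declared predictors; missing
#' cells are filled with the observed value of one of `donors` nearest
#' neighbours in predicted mean (regression parameters drawn from their
#' posterior, so imputations are proper).  Columns are visited in order of
#' ascending missingness for `maxit` sweeps; `m` independent chains give `m`
#' completed tables.  Observed cells are never altered.
#'
#' @param table data frame of numeric columns (`NA` = missing).
#' @param predictor_map named list: for each imputable column, the character
#'   vector of predictor columns.  Defaults to [mi_predictor_map()] applied
#'   to the wave columns present.
#' @param m number of imputed datasets.
#' @param donors donor-pool size (default 5).
#' @param maxit chained-equation sweeps per chain (default 10).
#' @param seed integer seed.
#' @return list of `m` completed data frames.
#' @export
pmm_impute <- function(table, predictor_map = NULL, m = 5L, donors = 5L,
                       maxit = 10L, seed = 1L) {
  table <- as.data.frame(table)
  if (is.null(predictor_map)) {
    predictor_map <- mi_predictor_map()
    predictor_map <- predictor_map[intersect(names(predictor_map), names(table))]
    predictor_map <- lapply(predictor_map, intersect, names(table))
  }
  targets <- names(predictor_map)[vapply(names(predictor_map),
                                         function(cl) anyNA(table[[cl]]), TRUE)]
  if (!length(targets)) return(replicate(m, table, simplify = FALSE))
  miss_frac <- vapply(targets, function(cl) mean(is.na(table[[cl]])), 1)
  targets <- targets[order(miss_frac)]
  obs_idx <- lapply(targets, function(cl) !is.na(table[[cl]]))
  names(obs_idx) <- targets
  for (cl in targets) {
    if (!all(predictor_map[[cl]] %in% names(table))) {
      stopf("predictors of %s missing from table", cl)
    }
    if (sum(obs_idx[[cl]]) < length(predictor_map[[cl]]) + 2L) {
      stopf("too few observed values in %s to fit its imputation model", cl)
    }
  }
  lapply(seq_len(m), function(chain) {
    with_seed(child_seed(seed, chain), {
      cur <- table
      for (cl in targets) {
        o <- obs_idx[[cl]]
        cur[[cl]][!o] <- sample(cur[[cl]][o], sum(!o), replace = TRUE)
      }
      for (it in seq_len(maxit)) {
        for (cl in targets) {
          o <- obs_idx[[cl]]
          X <- cbind(1, as.matrix(cur[, predictor_map[[cl]], drop = FALSE]))
          cur[[cl]][!o] <- pmm_update_column(table[[cl]], o, X, donors)
        }
      }
      cur
    })
  })
}

#' Pool correlation estimates across imputations (Rubin's rules)
#'
#' Estimates are combined on the Fisher-z scale: pooled point estimate is
#' the mean z, total variance is within (`1/(n-3)`) plus `(1 + 1/m)` times
#' the between-imputation variance, and the confidence interval uses the
#' Barnard-Rubin degrees of freedom before back-transforming.
#'
#' @param rs vector of per-imputation correlation estimates.
#' @param n complete sample size underlying each estimate.
#' @param conf confidence level (default 0.95).
#' @return list with `r`, `ci` (length 2), `m`, `z`, `se_z`,
#'   `within`, `between`.
#' @export
pool_correlations <- function(rs, n, conf = 0.95) {
  m <- length(rs)
  if (m < 1L) stopf("need at least one estimate")
  if (any(abs(rs) >= 1)) stopf("|r| = 1 cannot be pooled on the Fisher-z scale")
  z <- atanh(rs)
  within <- 1 / (n - 3)
  qbar <- mean(z)
  if (m == 1L) {
    tot <- within
    df <- Inf
    between <- 0
  } else {
    between <- stats::var(z)
    tot <- within + (1 + 1 / m) * between
    df <- if (between > 0) (m - 1) * (1 + within / ((1 + 1 / m) * between))^2 else Inf
  }
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf) / 2, df) else stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(qbar + c(-1, 1) * q * sqrt(tot))
  list(r = tanh(qbar), ci = ci, m = m, z = qbar, se_z = sqrt(tot),
       within = within, between = between)
}

#' Compare two dependent, non-overlapping correlations
#'
#' Tests `r_ab = r_cd` for correlations sharing the sample but no variable,
#' using Silver's modification of Dunn & Clark's z: the covariance term is
#' evaluated with both compared correlations replaced by the
#' backtransformed average Fisher z.
#'
#' @param r_ab,r_cd the two correlations to compare.
#' @param aux named vector of the four auxiliary correlations `r_ac`,
#'   `r_ad`, `r_bc`, `r_bd` (or a 4 x 4 correlation matrix in variable
#'   order a, b, c, d).
#' @param n sample size (>= 10).
#' @return list with `z`, `p` (two-sided), and the covariance term `c`.
#' @export
compare_dependent_correlations <- function(r_ab, r_cd, aux, n) {
  if (n < 10) stopf("n must be >= 10")
  if (is.matrix(aux)) {
    R <- aux
  } else {
    need <- c("r_ac", "r_ad", "r_bc", "r_bd")
    if (!all(need %in% names(aux))) {
      stopf("aux must name %s", paste(need, collapse = ", "))
    }
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- r_ab
    R[3, 4] <- R[4, 3] <- r_cd
    R[1, 3] <- R[3, 1] <- aux["r_ac"]
    R[1, 4] <- R[4, 1] <- aux["r_ad"]
    R[2, 3] <- R[3, 2] <- aux["r_bc"]
    R[2, 4] <- R[4, 2] <- aux["r_bd"]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("auxiliary correlation matrix is not positive semidefinite")
  r_ac <- R[1, 3]; r_ad <- R[1, 4]; r_bc <- R[2, 3]; r_bd <- R[2, 4]
  z1 <- atanh(r_ab)
  z2 <- atanh(r_cd)
  rbar <- tanh((z1 + z2) / 2)
  psi <- 0.5 * rbar * rbar * (r_ac^2 + r_ad^2 + r_bc^2 + r_bd^2) +
    r_ac * r_bd + r_ad * r_bc -
    (rbar * r_ac * r_ad + rbar * r_bc * r_bd +
       rbar * r_ac * r_bc + rbar * r_ad * r_bd)
  cterm <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cterm))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), c = cterm)
}

# ages at which the two trait series are paired for correlation (each age of
# the sparser series paired with the nearest age of the denser one)
trait_age_pairs <- function(spec = growth_spec()) {
  design <- build_design(spec)
  a_ages <- spec$ages[[spec$processes[1L]]]
  s_ages <- spec$ages[[spec$processes[2L]]]
  a_cols <- design$waves[design$proc == 1L]
  s_cols <- design$waves[design$proc == 2L]
  data.frame(
    label = s_ages,
    col_a = vapply(s_ages, function(a) a_cols[which.min(abs(a_ages - a))], ""),
    col_s = s_cols
  )
}

#' Class-stratified Spearman correlations between the two traits
#'
#' Computes the cross-trait Spearman correlation at each paired age, overall
#' and within each class stratum, optionally on multiply imputed data
#' (subjects complete at the first paired age are retained, later waves
#' imputed by [pmm_impute()], estimates pooled by [pool_correlations()]).
#' Each stratum also gets a first-age vs last-age comparison via
#' [compare_dependent_correlations()].
#'
#' @param cohort a `cohort_table`.
#' @param labels optional class labels (e.g. modal assignments) defining
#'   strata; `NULL` gives the overall analysis only.
#' @param spec a [growth_spec()].
#' @param pairs age-pairing table (default [trait_age_pairs()] of the spec).
#' @param impute impute incomplete later waves (`TRUE`) or use complete
#'   pairs per age (`FALSE`).
#' @param m,donors,maxit imputation controls.
#' @param seed integer seed.
#' @param min_pairs strata with fewer complete anchor pairs are flagged and
#'   skipped.
#' @return list with `report` (age, stratum, r, CI, n, m) and `comparisons`
#'   (stratum, r at first and last age, Silver z, p); skipped strata are
#'   listed in `flags`.
#' @export
stratified_correlations <- function(cohort, labels = NULL, spec = growth_spec(),
                                    pairs = NULL, impute = TRUE, m = 5L,
                                    donors = 5L, maxit = 5L, seed = 1L,
                                    min_pairs = 30L) {
  pairs <- pairs %||% trait_age_pairs(spec)
  dat <- as.data.frame(cohort)
  strata <- list(overall = seq_len(nrow(dat)))
  if (!is.null(labels)) {
    for (k in sort(unique(labels))) {
      strata[[paste0("class_", k)]] <- which(labels == k)
    }
  }
  report <- list()
  comparisons <- list()
  flags <- character(0)
  wave_cols <- unique(c(pairs$col_a, pairs$col_s))
  for (s in names(strata)) {
    rows <- strata[[s]]
    sub <- dat[rows, , drop = FALSE]
    anchor_ok <- !is.na(sub[[pairs$col_a[1L]]]) & !is.na(sub[[pairs$col_s[1L]]])
    sub <- sub[anchor_ok, , drop = FALSE]
    if (nrow(sub) < min_pairs) {
      flags <- c(flags, sprintf("stratum %s has %d complete anchor pairs (< %d); skipped",
                                s, nrow(sub), min_pairs))
      next
    }
    if (impute) {
      design <- build_design(spec)
      wide <- sub[, intersect(design$waves, names(sub)), drop = FALSE]
      imps <- pmm_impute(wide, m = m, donors = donors, maxit = maxit,
                         seed = child_seed(seed, match(s, names(strata))))
    } else {
      imps <- list(sub)
    }
    # per-imputation correlations at each age plus the aux correlations
    # between first- and last-age variables
    per_age <- matrix(NA_real_, length(imps), nrow(pairs))
    aux_mat <- matrix(NA_real_, length(imps), 4L)
    for (i in seq_along(imps)) {
      di <- imps[[i]]
      for (a in seq_len(nrow(pairs))) {
        per_age[i, a] <- tryCatch(
          as.numeric(spearman_cor(di[[pairs$col_a[a]]], di[[pairs$col_s[a]]])),
          error = function(e) NA_real_)
      }
      lastp <- nrow(pairs)
      aux_mat[i, ] <- c(
        scor_safe(di[[pairs$col_a[1L]]], di[[pairs$col_a[lastp]]]),
        scor_safe(di[[pairs$col_a[1L]]], di[[pairs$col_s[lastp]]]),
        scor_safe(di[[pairs$col_s[1L]]], di[[pairs$col_a[lastp]]]),
        scor_safe(di[[pairs$col_s[1L]]], di[[pairs$col_s[lastp]]]))
    }
    n_eff <- if (impute) nrow(sub) else NA_integer_
    for (a in seq_len(nrow(pairs))) {
      rs <- per_age[, a]
      rs <- rs[!is.na(rs)]
      if (!length(rs)) next
      na <- if (impute) nrow(sub) else
        sum(!is.na(sub[[pairs$col_a[a]]]) & !is.na(sub[[pairs$col_s[a]]]))
      pooled <- pool_correlations(pmin(pmax(rs, -0.9999), 0.9999), na)
      report[[length(report) + 1L]] <- data.frame(
        age = pairs$label[a], stratum = s, r = pooled$r,
        ci_low = pooled$ci[1L], ci_high = pooled$ci[2L], n = na,
        m = length(rs))
    }
    r1 <- mean(per_age[, 1L], na.rm = TRUE)
    r2 <- mean(per_age[, nrow(pairs)], na.rm = TRUE)
    aux <- colMeans(aux_mat, na.rm = TRUE)
    names(aux) <- c("r_ac", "r_ad", "r_bc", "r_bd")
    ncomp <- if (impute) nrow(sub) else
      sum(stats::complete.cases(sub[, c(pairs$col_a[c(1L, nrow(pairs))],
                                        pairs$col_s[c(1L, nrow(pairs))])]))
    cmp <- tryCatch(
      compare_dependent_correlations(r1, r2, aux, max(ncomp, 10L)),
      error = function(e) list(z = NA_real_, p = NA_real_))
    comparisons[[length(comparisons) + 1L]] <- data.frame(
      stratum = s, r_first = r1, r_last = r2, z = cmp$z, p = cmp$p, n = ncomp)
  }
  list(report = do.call(rbind, report),
       comparisons = do.call(rbind, comparisons),
       flags = flags)
}

scor_safe <- function(x, y) {
  tryCatch(as.numeric(spearman_cor(x, y)), error = function(e) NA_real_)
}
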