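# End-to-end orchestration: simulate or load a cohort, fit and enumerate
# trajectory classes, associate classes with auxiliary variables, run the
# correlation workflow, and write per-stage outputs plus a summary.

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML file path or a list.  See the package vignette for the
#' full schema; the main elements are `seed`, `out_dir`, `stages` (ordered
#' subset of `simulate`, `fit`, `associate`, `correlate`), `simulate`
#' (generator options or `NULL`), `cohort_path`, `k_max`, `rules`, `fit`,
#' `aux` (`binary`/`continuous` column names), and `correlate`.
#'
#' @param config list or YAML path.
#' @return validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% c("simulate", "fit", "associate", "correlate")
  known <- c("simulate", "fit", "associate", "correlate")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stopf("unknown stages: %s", paste(bad, collapse = ", "))
  ord <- match(config$stages, known)
  if (any(diff(ord) <= 0)) stopf("stages must follow the order simulate < fit < associate < correlate")
  needs_fit <- any(config$stages %in% c("associate", "correlate"))
  if (needs_fit && !"fit" %in% config$stages) {
    stopf("associate/correlate require the fit stage")
  }
  if ("fit" %in% config$stages && !"simulate" %in% config$stages &&
      is.null(config$cohort_path)) {
    stopf("fit requires either the simulate stage or a cohort_path")
  }
  config$k_max <- as.integer(config$k_max %||% 3L)
  config$rules <- utils::modifyList(list(alpha = 0.05, min_class_share = 0.05),
                                    config$rules %||% list())
  config$fit <- utils::modifyList(list(n_starts = 20L, n_final = 5L, tol = 1e-7),
                                  config$fit %||% list())
  config$correlate <- utils::modifyList(list(impute = FALSE, m = 5L),
                                        config$correlate %||% list())
  config
}

#' Run the full trajectory-analysis pipeline
#'
#' Executes the configured stages in order: cohort simulation (or loading),
#' class enumeration, three-step/BCH/DCAT association of auxiliary
#' variables, and the stratified correlation workflow.  Per-stage CSV/JSON
#' outputs, a run manifest (seeds, package version) and a Markdown summary
#' are written to `out_dir`.  A stage failure aborts the stages that depend
#' on it; independent stages continue.
#'
#' @param config list or YAML path, see [read_pipeline_config()].
#' @return invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out_dir <- cfg$out_dir %||% "trajmix_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- growth_spec()
  res <- list(config = cfg)

  if ("simulate" %in% cfg$stages) {
    sim_cfg <- cfg$simulate %||% list()
    gcfg <- default_generator_config(
      n_subjects = as.integer(sim_cfg$n_subjects %||% 1000L),
      seed = cfg$seed,
      missingness = sim_cfg$missingness %||% TRUE,
      aux = sim_cfg$aux %||% TRUE)
    gen <- generate_cohort(gcfg)
    res$cohort <- gen$cohort
    res$truth <- gen$truth
    write_cohort(gen$cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(data.frame(id = gen$cohort$id, class = gen$truth$labels),
                     file.path(out_dir, "truth_labels.csv"), row.names = FALSE)
    jsonlite::write_json(list(pi = gen$truth$pi, alpha = gen$truth$alpha,
                              theta = gen$truth$theta),
                         file.path(out_dir, "truth_params.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (!is.null(cfg$cohort_path)) {
    res$cohort <- load_cohort(cfg$cohort_path, spec)
  }

  if ("fit" %in% cfg$stages) {
    enum <- enumerate_classes(res$cohort, cfg$k_max, spec,
                              alpha = cfg$rules$alpha,
                              min_class_share = cfg$rules$min_class_share,
                              seed = cfg$seed,
                              n_starts = cfg$fit$n_starts,
                              n_final = cfg$fit$n_final, tol = cfg$fit$tol)
    res$enumeration <- enum
    utils::write.csv(enum$stats, file.path(out_dir, "selection.csv"),
                     row.names = FALSE)
    best <- enum$fits[[enum$recommended_k]]
    res$fit <- best
    if (inherits(best, "gmm_fit")) {
      utils::write.csv(data.frame(id = res$cohort$id, best$posteriors),
                       file.path(out_dir, "posteriors.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(K = best$K, pi = best$params$pi, alpha = best$params$alpha,
             Psi = best$params$Psi, theta = best$params$theta,
             loglik = best$loglik, n_parameters = best$n_parameters,
             converged = best$converged),
        file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  fit_ok <- inherits(res$fit %||% NULL, "gmm_fit")
  if ("associate" %in% cfg$stages) {
    if (!fit_ok) {
      res$associate <- "skipped: no usable fit"
    } else {
      res$associate <- tryCatch(
        associate_stage(res$cohort, res$fit, cfg, out_dir),
        error = function(e) paste("associate failed:", conditionMessage(e)))
    }
  }
  if ("correlate" %in% cfg$stages) {
    if (!fit_ok) {
      res$correlate <- "skipped: no usable fit"
    } else {
      labels <- modal_assignment(res$fit$posteriors)
      res$correlate <- tryCatch(
        stratified_correlations(res$cohort, labels, spec,
                                impute = isTRUE(cfg$correlate$impute),
                                m = cfg$correlate$m, seed = cfg$seed),
        error = function(e) paste("correlate failed:", conditionMessage(e)))
      if (is.list(res$correlate)) {
        utils::write.csv(res$correlate$report,
                         file.path(out_dir, "correlations.csv"), row.names = FALSE)
        utils::write.csv(res$correlate$comparisons,
                         file.path(out_dir, "correlation_comparisons.csv"),
                         row.names = FALSE)
      }
    }
  }

  jsonlite::write_json(
    list(seed = cfg$seed, stages = cfg$stages,
         package_version = as.character(utils::packageVersion("trajmix"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  write_summary_md(res, file.path(out_dir, "summary.md"))
  invisible(res)
}

associate_stage <- function(cohort, fit, cfg, out_dir) {
  aux <- cfg$aux %||% list()
  binary <- intersect(aux$binary %||% character(0), names(cohort))
  contin <- intersect(aux$continuous %||% character(0), names(cohort))
  if (!length(binary) && !length(contin)) {
    binary <- intersect(c("male", "low_income"), names(cohort))
    contin <- intersect("pgs_adhd", names(cohort))
  }
  labels <- modal_assignment(fit$posteriors)
  cem <- classification_error_matrix(fit$posteriors, labels)
  rows <- list()
  for (v in binary) {
    ts <- threestep_multinomial(labels, cem$Q, cohort[[v]])
    ts$variable <- v
    ts$analysis <- "threestep_or"
    rows[[length(rows) + 1L]] <- ts
    dp <- dcat_proportions(fit$posteriors, cohort[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      class = dp$proportions$class, reference = NA, log_odds = NA, se = dp$proportions$se,
      OR = NA, ci_low = NA, ci_high = NA, p = NA, n = dp$proportions$n,
      variable = v, analysis = "dcat_proportion")
    rows[[length(rows)]]$log_odds <- dp$proportions$proportion
  }
  bch_res <- list()
  W <- bch_weights(labels, cem$Q)
  for (v in contin) {
    bd <- bch_distal(W, cohort[[v]])
    bch_res[[v]] <- bd
    rows[[length(rows) + 1L]] <- data.frame(
      class = bd$means$class, reference = NA, log_odds = bd$means$mean,
      se = bd$means$se, OR = NA, ci_low = NA, ci_high = NA,
      p = bd$wald$p, n = bd$means$n, variable = v, analysis = "bch_mean")
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "aux_effects.csv"), row.names = FALSE)
  list(table = tab, Q = cem$Q, bch = bch_res)
}

write_summary_md <- function(res, path) {
  lines <- c("# Trajectory analysis summary", "")
  if (!is.null(res$enumeration)) {
    st <- res$enumeration$stats
    lines <- c(lines, "## Class enumeration", "",
               paste0("| K | loglik | AIC | BIC | entropy | smallest share | LRT p |"),
               "|---|--------|-----|-----|---------|----------------|-------|")
    for (i in seq_len(nrow(st))) {
      lines <- c(lines, sprintf("| %d | %.1f | %.1f | %.1f | %s | %s | %s |",
                                st$K[i], st$loglik[i], st$AIC[i], st$BIC[i],
                                fmt_or_dash(st$entropy[i]),
                                fmt_or_dash(st$smallest_class_share[i]),
                                fmt_or_dash(st$lmr_p[i], "%.4g")))
    }
    lines <- c(lines, "",
               sprintf("Recommended number of classes: **%d**",
                       res$enumeration$recommended_k), "")
  }
  if (inherits(res$fit %||% NULL, "gmm_fit")) {
    fit <- res$fit
    design <- fit$design
    Mu <- design$Lambda %*% t(fit$params$alpha)
    lines <- c(lines, "## Model-implied mean trajectories",
               "(screening cut-points: 6 on the 0-10 scale up to age 17, 4 at age 25; 9 on the 0-24 scale)",
               "",
               paste0("| wave | ", paste(sprintf("class_%d (share %.2f)",
                                                 seq_len(fit$K), fit$params$pi),
                                         collapse = " | "), " |"),
               paste0("|------|", paste(rep("------|", fit$K), collapse = "")))
    for (j in seq_len(nrow(Mu))) {
      lines <- c(lines, sprintf("| %s | %s |", design$waves[j],
                                paste(sprintf("%.2f", Mu[j, ]), collapse = " | ")))
    }
    lines <- c(lines, "")
  }
  if (is.list(res$correlate %||% NULL) && !is.null(res$correlate$comparisons)) {
    cmp <- res$correlate$comparisons
    lines <- c(lines, "## Cross-trait correlations, first vs last age", "")
    for (i in seq_len(nrow(cmp))) {
      lines <- c(lines, sprintf("- %s: r = %.2f to %.2f (z = %.2f, p = %.3g)",
                                cmp$stratum[i], cmp$r_first[i], cmp$r_last[i],
                                cmp$z[i], cmp$p[i]))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
}

fmt_or_dash <- function(x, fmt = "%.3f") {
  if (is.na(x)) "-" else sprintf(fmt, x)
}

#' Refit the enumeration separately within the levels of a binary stratum
#'
#' Runs [enumerate_classes()] independently per stratum (e.g. per sex) and
#' reports the recommended K and mean trajectories for each.
#'
#' @param config pipeline config (list or YAML path); must simulate or point
#'   to a cohort containing `stratum_column`.
#' @param stratum_column name of a binary 0/1 column.
#' @param min_n strata smaller than this are refused (default 200).
#' @return named list of per-stratum enumeration results.
#' @export
sex_stratified_refit <- function(config, stratum_column, min_n = 200L) {
  cfg <- read_pipeline_config(config)
  spec <- growth_spec()
  if ("simulate" %in% cfg$stages) {
    sim_cfg <- cfg$simulate %||% list()
    gcfg <- default_generator_config(
      n_subjects = as.integer(sim_cfg$n_subjects %||% 1000L),
      seed = cfg$seed, missingness = sim_cfg$missingness %||% TRUE,
      aux = TRUE)
    cohort <- generate_cohort(gcfg)$cohort
  } else {
    cohort <- load_cohort(cfg$cohort_path, spec)
  }
  if (!stratum_column %in% names(cohort)) {
    stopf("stratum column %s not found", stratum_column)
  }
  g <- cohort[[stratum_column]]
  if (!all(stats::na.omit(g) %in% c(0, 1))) stopf("stratum column must be binary 0/1")
  out <- list()
  for (lev in c(0, 1)) {
    idx <- which(!is.na(g) & g == lev)
    if (length(idx) < min_n) {
      stopf("stratum %s = %d has n = %d (< %d)", stratum_column, lev,
            length(idx), min_n)
    }
    out[[paste0(stratum_column, "_", lev)]] <- enumerate_classes(
      cohort[idx, , drop = FALSE], cfg$k_max, spec,
      alpha = cfg$rules$alpha, min_class_share = cfg$rules$min_class_share,
      seed = child_seed(cfg$seed, lev + 1), n_starts = cfg$fit$n_starts,
      n_final = cfg$fit$n_final, tol = cfg$fit$tol)
  }
  out
}
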