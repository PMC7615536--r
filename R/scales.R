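# Questionnaire scale definitions, item scoring with the missing-item rule,
# score banding, and cohort table reading/writing.

#' Define a questionnaire scale
#'
#' @param name scale identifier.
#' @param n_items number of items.
#' @param item_range `c(min, max)` per item.
#' @param total_range `c(min, max)` of the total score; must be consistent
#'   with `n_items * item max`.
#' @param max_missing_items questionnaires with more missing items than this
#'   are scored missing (default 2).
#' @param band_rules list of banding rules, each
#'   `list(rater =, ages = c(min, max), bands = data.frame(lo, hi, label))`;
#'   within a rule the band intervals must partition the total range.
#' @return an object of class `scale_def`.
#' @export
scale_def <- function(name, n_items, item_range, total_range,
                      max_missing_items = 2L, band_rules = list()) {
  if (total_range[2L] != n_items * item_range[2L] ||
      total_range[1L] != n_items * item_range[1L]) {
    stopf("total_range inconsistent with n_items x item range")
  }
  for (r in band_rules) {
    b <- r$bands[order(r$bands$lo), ]
    if (b$lo[1L] != total_range[1L] || b$hi[nrow(b)] != total_range[2L] ||
        (nrow(b) > 1L && any(b$lo[-1L] != b$hi[-nrow(b)] + 1L))) {
      stopf("band intervals must partition the total range without overlap")
    }
  }
  structure(list(name = name, n_items = as.integer(n_items),
                 item_range = item_range, total_range = total_range,
                 max_missing_items = as.integer(max_missing_items),
                 band_rules = band_rules),
            class = "scale_def")
}

band <- function(lo, hi, label) data.frame(lo = lo, hi = hi, label = label)

#' Built-in ADHD-symptom subscale (5 items scored 0-2, total 0-10)
#'
#' Parent-rated bands up to age 17: 0-5 low, 6-7 slightly raised, 8-10
#' high.  At age 25: parent report >= 4 is "raised"; self report 5 is
#' "slightly raised" and >= 6 "high".
#' @return a [scale_def()].
#' @export
sdq_adhd_scale <- function() {
  scale_def(
    "sdq_adhd", n_items = 5L, item_range = c(0L, 2L), total_range = c(0L, 10L),
    band_rules = list(
      list(rater = "parent", ages = c(2, 17),
           bands = rbind(band(0, 5, "low"), band(6, 7, "slightly raised"),
                         band(8, 10, "high"))),
      list(rater = "parent", ages = c(18, 99),
           bands = rbind(band(0, 3, "low"), band(4, 10, "raised"))),
      list(rater = "self", ages = c(18, 99),
           bands = rbind(band(0, 4, "low"), band(5, 5, "slightly raised"),
                         band(6, 10, "high")))
    ))
}

#' Built-in social-communication checklist (12 items scored 0-2, total 0-24)
#'
#' A total of 9 or more is above the conventional cut-point at any age and
#' for any rater.
#' @return a [scale_def()].
#' @export
scdc_scale <- function() {
  scale_def(
    "scdc", n_items = 12L, item_range = c(0L, 2L), total_range = c(0L, 24L),
    band_rules = list(
      list(rater = "any", ages = c(0, 99),
           bands = rbind(band(0, 8, "below cut-point"),
                         band(9, 24, "above cut-point")))
    ))
}

#' Score a questionnaire from item responses
#'
#' Returns the prorated total: if more than `max_missing_items` items are
#' missing the score is missing; otherwise the mean of the observed items is
#' scaled to the full item count, rounded half-up and clipped to the total
#' range.  With no missing items this is the plain item sum.
#'
#' @param items numeric vector of item responses (`NA` = missing), length
#'   `scale$n_items`.
#' @param scale a [scale_def()].
#' @return integer total score or `NA`.
#' @export
score_questionnaire <- function(items, scale) {
  if (length(items) != scale$n_items) {
    stopf("expected %d items for scale %s", scale$n_items, scale$name)
  }
  obs <- items[!is.na(items)]
  if (any(obs < scale$item_range[1L] | obs > scale$item_range[2L])) {
    stopf("item response outside range [%d, %d]", scale$item_range[1L],
          scale$item_range[2L])
  }
  if (sum(is.na(items)) > scale$max_missing_items) return(NA_integer_)
  total <- round_half_up(mean(obs) * scale$n_items)
  as.integer(min(max(total, scale$total_range[1L]), scale$total_range[2L]))
}

#' Band label for a total score
#'
#' @param scale a [scale_def()].
#' @param rater rater identity (e.g. `"parent"`, `"self"`); rules with rater
#'   `"any"` match every rater.
#' @param age age in years.
#' @param score total score within the scale's range.
#' @return the band label whose interval contains the score.
#' @export
band_for_score <- function(scale, rater, age, score) {
  if (score < scale$total_range[1L] || score > scale$total_range[2L]) {
    stopf("score %s outside total range of scale %s", score, scale$name)
  }
  for (r in scale$band_rules) {
    if ((identical(r$rater, "any") || identical(r$rater, rater)) &&
        age >= r$ages[1L] && age <= r$ages[2L]) {
      hit <- r$bands$lo <= score & score <= r$bands$hi
      return(r$bands$label[hit][1L])
    }
  }
  stopf("no band rule for scale %s, rater %s, age %s", scale$name, rater, age)
}

#' Read a wide cohort CSV
#'
#' Expects one row per subject with an `id` column, the wave columns of the
#' growth spec (`A_4 ... A_25`, `S_7 ... S_25`; empty cells = missing) and
#' optionally declared auxiliary columns.  Subjects with no observed trait
#' score at any wave are excluded (count in the `n_excluded` attribute).
#'
#' @param path CSV file path.
#' @param spec a [growth_spec()] declaring the measurement design.
#' @param aux_columns character vector of expected auxiliary columns; when
#'   supplied, any column outside `id` + waves + `aux_columns` is an error.
#'   When `NULL`, extra columns are accepted as auxiliaries.
#' @return a `cohort_table` data frame.
#' @export
load_cohort <- function(path, spec = growth_spec(), aux_columns = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  design <- build_design(spec)
  if (!"id" %in% names(raw)) stopf("cohort file lacks an `id` column")
  miss <- setdiff(design$waves, names(raw))
  if (length(miss)) stopf("cohort file lacks wave columns: %s", paste(miss, collapse = ", "))
  extra <- setdiff(names(raw), c("id", design$waves))
  if (!is.null(aux_columns)) {
    unknown <- setdiff(extra, aux_columns)
    if (length(unknown)) stopf("unknown columns: %s", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(raw$id)) stopf("duplicate subject ids")
  out <- data.frame(id = raw$id, check.names = FALSE)
  for (cl in c(design$waves, extra)) {
    v <- raw[[cl]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num))) stopf("malformed numeric cell in column %s", cl)
    out[[cl]] <- num
  }
  for (i in seq_along(spec$processes)) {
    rng <- spec$ranges[[spec$processes[i]]]
    for (cl in design$waves[design$proc == i]) {
      bad <- !is.na(out[[cl]]) & (out[[cl]] < rng[1L] | out[[cl]] > rng[2L])
      if (any(bad)) stopf("score outside [%d, %d] in column %s", rng[1L], rng[2L], cl)
    }
  }
  Y <- as.matrix(out[, design$waves])
  keep <- rowSums(!is.na(Y)) > 0L
  n_excluded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a cohort table as wide CSV
#'
#' Missing cells are written as empty strings.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
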