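#' Association statistics for a pooled diagnosis-by-level table
#'
#' `chi_square()` runs the Pearson chi-square test of association between
#' diagnosis class and predictor level on a pooled 2 x K table, without
#' continuity correction (the convention under which the pooled summary
#' statistics of the source tables are reproduced). `likelihood_ratio()`
#' returns the diagnostic likelihood ratio
#' \eqn{P(\mathrm{level} \mid \mathrm{cardiac}) / P(\mathrm{level} \mid \mathrm{noncardiac})}
#' for a binary predictor, computed from the exact pooled counts (never from
#' rounded percentages). By convention it is reported at the
#' cardiac-pointing level: presence for supine syncope, effort syncope,
#' male sex and "two spells or less"; absence for nausea, diaphoresis,
#' prodrome and blurred vision.
#'
#' @param pooled a `pooled_table` from [pool_counts()].
#' @param level level at which to evaluate the likelihood ratio; defaults to
#'   the predictor's cardiac-pointing level.
#' @return `chi_square()`: a list with `chi2`, `df` (= K - 1) and `p_value`.
#'   `likelihood_ratio()`: a positive number.
#' @examples
#' counts <- syncope_fixture_counts()
#' chi_square(pool_counts(counts, "gender"))     # chi2 ~ 25.4
#' likelihood_ratio(pool_counts(counts, "effort_syncope"))  # ~ 6.92
#' @export
chi_square <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_table"))
  if (pooled$grand_total <= 0 || any(pooled$row_totals == 0) ||
      any(pooled$col_totals == 0)) {
    stop("degenerate table for '", pooled$predictor$name,
         "': a zero marginal makes expected counts zero")
  }
  ct <- suppressWarnings(stats::chisq.test(pooled$counts, correct = FALSE))
  list(
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value)
  )
}

#' @rdname chi_square
#' @export
likelihood_ratio <- function(pooled, level = NULL) {
  stopifnot(inherits(pooled, "pooled_table"))
  if (ncol(pooled$counts) != 2L) {
    stop("likelihood ratio is only reported for binary predictors; '",
         pooled$predictor$name, "' has ", ncol(pooled$counts), " levels")
  }
  if (is.null(level)) level <- pooled$predictor$cardiac_level
  if (!level %in% pooled$predictor$levels) {
    stop("'", level, "' is not a level of '", pooled$predictor$name, "'")
  }
  tot <- pooled$row_totals
  if (any(tot == 0)) {
    stop("degenerate table for '", pooled$predictor$name,
         "': a class total is zero")
  }
  p1 <- pooled$counts["cardiac", level] / tot["cardiac"]
  p0 <- pooled$counts["noncardiac", level] / tot["noncardiac"]
  if (p0 == 0) {
    stop("undefined likelihood ratio for '", pooled$predictor$name,
         "' at level '", level, "': zero probability under noncardiac")
  }
  unname(p1 / p0)
}

#' Pooled association table across all predictors
#'
#' Pools every predictor present in a long count table and assembles the
#' per-predictor association summary: pooled counts at the cardiac-pointing
#' level, chi-square statistic, degrees of freedom, p-value, and (for
#' binary predictors) the diagnostic likelihood ratio. Three-level
#' predictors (age) get `NA` in the likelihood-ratio column.
#'
#' @inheritParams pool_counts
#' @return A `data.frame` with one row per predictor: `predictor`, `chi2`,
#'   `df`, `p_value`, `likelihood_ratio`, and the pooled class totals.
#' @examples
#' association_table(syncope_fixture_counts())
#' @export
association_table <- function(counts, predictors = syncope_predictors()) {
  counts <- validate_count_table(counts, predictors)
  present <- intersect(names(predictors), unique(counts$predictor))
  rows <- lapply(present, function(p) {
    pooled <- pool_counts(counts, p, predictors)
    a <- chi_square(pooled)
    lr <- if (ncol(pooled$counts) == 2L) likelihood_ratio(pooled) else NA_real_
    data.frame(
      predictor = p,
      n_cardiac = unname(pooled$row_totals["cardiac"]),
      n_noncardiac = unname(pooled$row_totals["noncardiac"]),
      chi2 = a$chi2, df = a$df, p_value = a$p_value,
      likelihood_ratio = lr,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Apply the literature-based predictor selection rule
#'
#' A candidate predictor is retained when (i) the source literature reports
#' a statistically significant association with the diagnosis in at least
#' `min_studies` studies and (ii) the pooled association is significant at
#' `alpha`. The per-study significance sets are supplied as metadata (taken
#' from the source publications, several of which reported multivariable
#' significance without a cross-tabulation); they are not recomputed from
#' counts. Bystander-observed signs never enter the candidate list.
#'
#' @param assoc association table from [association_table()].
#' @param significance `data.frame` with columns `predictor`, `study_id`:
#'   one row per study reporting a significant association.
#' @param min_studies minimum number of significant source studies (default 3).
#' @param alpha pooled significance threshold (default 0.05).
#' @return Character vector of retained predictor names, in registry order.
#' @examples
#' assoc <- association_table(syncope_fixture_counts())
#' select_predictors(assoc, syncope_fixture_significance())
#' @export
select_predictors <- function(assoc, significance, min_studies = 3,
                              alpha = 0.05) {
  stopifnot(all(c("predictor", "p_value") %in% names(assoc)),
            all(c("predictor", "study_id") %in% names(significance)))
  n_sig <- table(unique(significance[c("predictor", "study_id")])$predictor)
  keep <- vapply(seq_len(nrow(assoc)), function(i) {
    p <- assoc$predictor[i]
    n <- if (p %in% names(n_sig)) n_sig[[p]] else 0L
    n >= min_studies && assoc$p_value[i] < alpha
  }, logical(1))
  assoc$predictor[keep]
}

#' Write the association report
#'
#' Mirrors the pooled summary columns of the source overview table:
#' predictor, chi-square, degrees of freedom, p-value and likelihood ratio
#' (rounded to 2 decimals for reporting; `NA` for 3-level predictors).
#'
#' @param assoc association table from [association_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(assoc, path) {
  out <- assoc
  out$chi2 <- round(out$chi2, 1)
  out$p_value <- signif(out$p_value, 2)
  out$likelihood_ratio <- round(out$likelihood_ratio, 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
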