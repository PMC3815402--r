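#' Stratified standardization plan
#'
#' A resampling plan standardizes a cohort to a reference joint
#' distribution of stratification variables (age band by number-of-spells
#' band in the published design, to attenuate accrual bias). Stratum
#' targets are converted to integer per-replicate counts by the
#' largest-remainder method, so the counts always sum exactly to the
#' replicate size.
#'
#' `default_resample_plan()` builds the documented default: the reference
#' distribution is the product of the pooled literature marginals of age
#' and spells (the source tables print no joint distribution — a gap the
#' plan interface exists to override).
#'
#' @param targets `data.frame` of stratum definitions: one column per
#'   stratification variable plus a `proportion` column summing to 1.
#' @param n_replicates number of replicates to draw; default 1000.
#' @param replicate_size patients per replicate, or `NULL` (default) for
#'   the source cohort size.
#' @param seed integer seed driving all resampling randomness.
#' @return An object of class `resample_plan`.
#' @examples
#' default_resample_plan(n_replicates = 10, seed = 42)
#' @export
resample_plan <- function(targets, n_replicates = 1000,
                          replicate_size = NULL, seed = 1) {
  stopifnot(is.data.frame(targets), "proportion" %in% names(targets),
            nrow(targets) > 0L, n_replicates >= 1L,
            is.null(replicate_size) || replicate_size >= 1L)
  if (abs(sum(targets$proportion) - 1) > 1e-8) {
    stop("stratum target proportions must sum to 1")
  }
  if (any(targets$proportion < 0)) stop("negative target proportion")
  vars <- setdiff(names(targets), "proportion")
  if (length(vars) == 0L) stop("targets need at least one stratum variable")
  if (anyDuplicated(targets[vars])) stop("duplicated stratum definition")
  structure(
    list(targets = targets, strata_vars = vars,
         n_replicates = as.integer(n_replicates),
         replicate_size = if (is.null(replicate_size)) NULL
                          else as.integer(replicate_size),
         seed = as.integer(seed)),
    class = "resample_plan"
  )
}

#' @rdname resample_plan
#' @export
default_resample_plan <- function(n_replicates = 1000,
                                  replicate_size = NULL, seed = 1) {
  counts <- syncope_fixture_counts()
  age <- pool_counts(counts, "age")
  spells <- pool_counts(counts, "spells")
  p_age <- age$col_totals / age$grand_total
  p_spells <- spells$col_totals / spells$grand_total
  targets <- expand.grid(age = names(p_age), spells = names(p_spells),
                         stringsAsFactors = FALSE)
  targets$proportion <- p_age[targets$age] * p_spells[targets$spells]
  resample_plan(targets, n_replicates, replicate_size, seed)
}

#' @export
print.resample_plan <- function(x, ...) {
  cat("Resampling plan: ", x$n_replicates, " replicates of ",
      if (is.null(x$replicate_size)) "source-cohort size"
      else x$replicate_size,
      ", seed ", x$seed, "\n", sep = "")
  print(x$targets, row.names = FALSE)
  invisible(x)
}

# floor + distribute the residual to the largest fractional remainders
largest_remainder <- function(proportions, size) {
  raw <- proportions * size
  cnt <- floor(raw)
  short <- size - sum(cnt)
  if (short > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}

#' Draw standardized replicates of a cohort
#'
#' Each replicate is drawn with replacement *within* strata so that its
#' stratum composition matches the plan's target distribution exactly
#' (largest-remainder rounding of `proportion * replicate_size`).
#' Replicates are stored as row-index vectors into the source cohort;
#' `replicate_cohort()` materializes one. A plan with a positive target in
#' a stratum the cohort does not cover is infeasible and raises an error.
#' Given the same plan (including its seed), the draw is bit-reproducible.
#'
#' @param cohort source patient `data.frame`; must contain the plan's
#'   stratification variables.
#' @param plan a [resample_plan].
#' @return An object of class `syncope_resamples`: list with `indices`
#'   (list of integer vectors), the source `cohort`, the `plan` and the
#'   per-stratum `counts`.
#' @examples
#' cohort <- data.frame(age = sample(c("lt40", "ge60"), 100, TRUE),
#'                      spells = sample(c("le2", "gt2"), 100, TRUE))
#' plan <- resample_plan(
#'   expand.grid(age = c("lt40", "ge60"), spells = c("le2", "gt2"),
#'               proportion = 0.25, stringsAsFactors = FALSE),
#'   n_replicates = 5, seed = 7)
#' rs <- standardized_resample(cohort, plan)
#' nrow(replicate_cohort(rs, 1))
#' @export
standardized_resample <- function(cohort, plan) {
  stopifnot(inherits(plan, "resample_plan"), is.data.frame(cohort))
  miss <- setdiff(plan$strata_vars, names(cohort))
  if (length(miss) > 0L) {
    stop("cohort lacks stratification variable(s): ",
         paste(miss, collapse = ", "))
  }
  size <- if (is.null(plan$replicate_size)) nrow(cohort)
          else plan$replicate_size
  counts <- largest_remainder(plan$targets$proportion, size)

  key <- function(df) do.call(paste, c(df[plan$strata_vars], sep = "\r"))
  cohort_key <- key(cohort)
  strata_key <- key(plan$targets)
  members <- lapply(strata_key, function(k) which(cohort_key == k))
  empty <- counts > 0L & vapply(members, length, integer(1)) == 0L
  if (any(empty)) {
    bad <- plan$targets[which(empty)[1L], plan$strata_vars, drop = FALSE]
    stop("infeasible plan: stratum (",
         paste(unlist(bad), collapse = ", "),
         ") has a positive target but no patients in the cohort")
  }

  set.seed(plan$seed)
  indices <- lapply(seq_len(plan$n_replicates), function(r) {
    unlist(lapply(seq_along(members), function(s) {
      if (counts[s] == 0L) return(integer(0))
      members[[s]][sample.int(length(members[[s]]), counts[s],
                              replace = TRUE)]
    }))
  })
  structure(
    list(indices = indices, cohort = cohort, plan = plan,
         counts = stats::setNames(counts, strata_key)),
    class = "syncope_resamples"
  )
}

#' @rdname standardized_resample
#' @param resamples a `syncope_resamples` object.
#' @param i replicate number.
#' @export
replicate_cohort <- function(resamples, i) {
  stopifnot(inherits(resamples, "syncope_resamples"))
  resamples$cohort[resamples$indices[[i]], , drop = FALSE]
}

#' @export
length.syncope_resamples <- function(x) length(x$indices)

#' @export
print.syncope_resamples <- function(x, ...) {
  cat("Standardized resamples:", length(x$indices), "replicates of",
      sum(x$counts), "patients (seed", paste0(x$plan$seed, ")"), "\n")
  invisible(x)
}

#' Evaluate a metric on every replicate
#'
#' Applies a score-based metric (default [c_statistic()]) to each
#' replicate, given per-patient scores and true labels aligned with the
#' source cohort rows. Computing scores once on the source cohort and
#' indexing them per replicate is exact, because resampling only repeats
#' rows.
#'
#' @inheritParams replicate_cohort
#' @param scores numeric score per source-cohort row.
#' @param labels true class per source-cohort row.
#' @param metric `function(scores, labels)` returning a scalar.
#' @return Numeric vector, one value per replicate.
#' @export
replicate_metrics <- function(resamples, scores, labels,
                              metric = c_statistic) {
  stopifnot(inherits(resamples, "syncope_resamples"),
            length(scores) == nrow(resamples$cohort),
            length(labels) == nrow(resamples$cohort))
  vapply(resamples$indices, function(idx) metric(scores[idx], labels[idx]),
         numeric(1))
}

#' Summarize a replicate metric distribution
#'
#' @param x numeric vector of per-replicate metric values (>= 1 value).
#' @param probs quantile probabilities to report.
#' @return Named list: `n`, `mean`, `sd`, and the requested quantiles.
#' @examples
#' summarize_replicates(c(0.6, 0.8))
#' @export
summarize_replicates <- function(x, probs = c(0.025, 0.25, 0.5, 0.75,
                                              0.975)) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  c(list(n = length(x), mean = mean(x), sd = stats::sd(x)),
    as.list(stats::quantile(x, probs)))
}
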