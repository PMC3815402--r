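#' Bundled literature and test-population fixtures
#'
#' The package ships the substance of the source publication tables as
#' plain-text fixtures under `inst/extdata/`:
#'
#' * `syncope_fixture_counts()` — the per-study predictor-by-diagnosis
#'   counts of the derivation overview table (seven studies, eleven
#'   candidate predictors). Two rows are carried as printed pooled totals
#'   under `study_id = "pooled"` rather than per-study cells: *age*, whose
#'   printed per-study cells are internally inconsistent with the printed
#'   totals (the totals, not the cell sums, reproduce the printed pooled
#'   chi-square of 171.7), and *diaphoresis*, whose per-study cells are
#'   inconsistent with the printed totals (the totals reproduce the printed
#'   chi-square 92.6 and likelihood ratio 1.42). For both, the printed
#'   totals are treated as authoritative.
#' * `syncope_fixture_significance()` — per-study significance metadata for
#'   the selection rule. The source publications report which studies found
#'   each predictor significant, but not in a recoverable tabular form, so
#'   this file is a **synthetic reconstruction** (every candidate credited
#'   with >= 3 significant studies, matching the narrative that eleven
#'   candidates were significant in three or more studies; palpitations is
#'   then excluded by the pooled-significance rule).
#' * `syncope_fixture_populations()` — the four test-population
#'   distribution tables (counts per predictor, class and level).
#' * `syncope_fixture_priors()` — prior prevalence of cardiac syncope per
#'   test population, as exact fractions of the class sizes
#'   (e.g. calgary 138/663).
#'
#' @return A `data.frame` (counts, significance, populations) or a named
#'   numeric vector (priors).
#' @export
syncope_fixture_counts <- function() {
  read_count_table(syncope_extdata("derivation_counts.csv"))
}

#' @rdname syncope_fixture_counts
#' @export
syncope_fixture_significance <- function() {
  utils::read.csv(syncope_extdata("study_significance_synthetic.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname syncope_fixture_counts
#' @export
syncope_fixture_populations <- function() {
  x <- utils::read.csv(syncope_extdata("test_population_counts.csv"),
                       stringsAsFactors = FALSE)
  x$count <- as.integer(x$count)
  x
}

#' @rdname syncope_fixture_counts
#' @export
syncope_fixture_priors <- function() {
  x <- utils::read.csv(syncope_extdata("test_population_sizes.csv"),
                       stringsAsFactors = FALSE)
  stats::setNames(x$cardiac_n / (x$cardiac_n + x$noncardiac_n), x$population)
}

syncope_fixture_sizes <- function() {
  utils::read.csv(syncope_extdata("test_population_sizes.csv"),
                  stringsAsFactors = FALSE)
}

syncope_extdata <- function(file) {
  path <- system.file("extdata", file, package = "syncopenb")
  if (!nzchar(path)) stop("bundled fixture not found: ", file)
  path
}
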