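#' Read a long-format study count table
#'
#' Literature count tables are exchanged as long-format CSV/TSV with columns
#' `study_id, predictor, class, level, count`: one row per study x predictor
#' x diagnosis class x level cell. A study that did not report a predictor
#' simply has no rows for it.
#'
#' @param path CSV (comma) or TSV (tab) file; the delimiter is chosen by
#'   file extension (`.tsv`/`.tab` means tab).
#' @param predictors predictor registry the table must conform to; defaults
#'   to [syncope_predictors()].
#' @return A validated `data.frame` with the five columns above.
#' @seealso [pool_counts()], [syncope_fixture_counts()]
#' @export
read_count_table <- function(path, predictors = syncope_predictors()) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character")
  validate_count_table(x, predictors, context = path)
}

validate_count_table <- function(x, predictors = syncope_predictors(),
                                 context = "count table") {
  need <- c("study_id", "predictor", "class", "level", "count")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop(context, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  x <- x[need]
  x$count <- suppressWarnings(as.numeric(x$count))
  bad <- which(!is.finite(x$count) | x$count < 0 | x$count != round(x$count))
  if (length(bad) > 0L) {
    stop(context, ": non-integer or negative count at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  x$count <- as.integer(x$count)
  bad <- which(!x$class %in% .classes)
  if (length(bad) > 0L) {
    stop(context, ": unknown class '", x$class[bad[1L]], "' at row ", bad[1L])
  }
  bad <- which(!x$predictor %in% names(predictors))
  if (length(bad) > 0L) {
    stop(context, ": unknown predictor '", x$predictor[bad[1L]],
         "' at row ", bad[1L])
  }
  for (p in unique(x$predictor)) {
    lv <- predictors[[p]]$levels
    found <- x$level[x$predictor == p]
    if (!all(found %in% lv)) {
      stop(context, ": predictor '", p, "' has level(s) ",
           paste(setdiff(found, lv), collapse = ", "),
           " outside its registry levels (", paste(lv, collapse = ", "), ")")
    }
  }
  x
}

#' Pool per-study counts into a single diagnosis-by-level table
#'
#' The class-conditional evidence for each predictor is pooled across
#' source studies by plain summation of the reported frequencies: each cell
#' of the pooled 2 x K table is the sum of that cell over the studies that
#' reported the predictor; non-reporting studies contribute nothing.
#' Pooling is associative and order-independent.
#'
#' @param counts a long count table (see [read_count_table()]); may contain
#'   several predictors, in which case `predictor` selects one.
#' @param predictor name of the predictor to pool; may be omitted when
#'   `counts` holds a single predictor.
#' @param predictors predictor registry.
#' @return A `pooled_table`: the 2 x K integer count matrix (rows `cardiac`,
#'   `noncardiac`; columns the predictor's levels) with class totals, level
#'   totals and grand total attached.
#' @examples
#' counts <- syncope_fixture_counts()
#' pool_counts(counts, "supine_syncope")
#' @export
pool_counts <- function(counts, predictor = NULL,
                        predictors = syncope_predictors()) {
  counts <- validate_count_table(counts, predictors)
  if (is.null(predictor)) {
    predictor <- unique(counts$predictor)
    if (length(predictor) != 1L) {
      stop("counts contain ", length(predictor),
           " predictors; supply `predictor`")
    }
  }
  spec <- predictors[[predictor]]
  if (is.null(spec)) stop("unknown predictor '", predictor, "'")
  x <- counts[counts$predictor == predictor, , drop = FALSE]
  if (nrow(x) == 0L) stop("no counts for predictor '", predictor, "'")
  m <- matrix(0L, nrow = 2L, ncol = length(spec$levels),
              dimnames = list(.classes, spec$levels))
  for (i in seq_len(nrow(x))) {
    m[x$class[i], x$level[i]] <- m[x$class[i], x$level[i]] + x$count[i]
  }
  pooled_table(spec, m)
}

pooled_table <- function(spec, counts) {
  stopifnot(identical(rownames(counts), .classes),
            identical(colnames(counts), spec$levels),
            all(counts >= 0))
  structure(
    list(
      predictor = spec,
      counts = counts,
      row_totals = rowSums(counts),
      col_totals = colSums(counts),
      grand_total = sum(counts)
    ),
    class = "pooled_table"
  )
}

#' @export
print.pooled_table <- function(x, ...) {
  cat("Pooled counts for '", x$predictor$name, "' (n = ", x$grand_total,
      ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Reconstruct age-bin counts from a reported mean and SD
#'
#' Some source studies report age only as mean +/- SD. Patients are
#' allocated to age bins by the normal cumulative distribution with that
#' mean and SD, each bin is rounded to the nearest integer, and any
#' rounding residual is reconciled into the largest bin so that the counts
#' sum exactly to `n`. With `sd = 0` all patients fall in the bin containing
#' the mean (an edge value belongs to the upper bin, matching the
#' `<40 / 40-60 / >=60` convention that places age 60 in the oldest bin).
#'
#' @param n number of patients (> 0).
#' @param mean,sd reported mean and standard deviation of age, in years
#'   (`sd >= 0`).
#' @param bin_edges strictly increasing interior cut points; `length(bin_edges) + 1`
#'   bins result. Default `c(40, 60)` gives the model's three age bins.
#' @return Integer vector of bin counts summing to `n`.
#' @examples
#' counts_from_mean_sd(341, 61, 20)
#' @export
counts_from_mean_sd <- function(n, mean, sd, bin_edges = c(40, 60)) {
  stopifnot(length(n) == 1L, n > 0, n == round(n), sd >= 0,
            length(bin_edges) >= 1L, !is.unsorted(bin_edges, strictly = TRUE))
  k <- length(bin_edges) + 1L
  if (sd == 0) {
    cnt <- integer(k)
    cnt[findInterval(mean, bin_edges) + 1L] <- as.integer(n)
    return(cnt)
  }
  p <- diff(c(0, stats::pnorm(bin_edges, mean, sd), 1))
  cnt <- round(n * p)
  resid <- n - sum(cnt)
  if (resid != 0) {
    big <- which.max(cnt)
    cnt[big] <- cnt[big] + resid
  }
  as.integer(cnt)
}
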