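#' Conditional probability tables with population priors
#'
#' The parameter set of the diagnostic model: for every modelled predictor a
#' 2 x K table of class-conditional level probabilities
#' \eqn{P(\mathrm{level} \mid \mathrm{class})}, plus the prior probability
#' of cardiac syncope for each patient population. Each row of each table
#' must sum to 1 (within 1e-12) and every prior must lie strictly between 0
#' and 1.
#'
#' @param cpt named list of 2 x K probability matrices (rows `cardiac`,
#'   `noncardiac`; columns the predictor's levels).
#' @param priors named numeric vector of P(cardiac) per population.
#' @param predictors predictor registry the tables refer to.
#' @return An object of class `syncope_cpts`.
#' @seealso [derive_cpts()], [fit_cpts_from_cohort()], [write_cpts()]
#' @export
syncope_cpts <- function(cpt, priors, predictors = syncope_predictors()) {
  stopifnot(is.list(cpt), length(cpt) > 0L, !is.null(names(cpt)),
            is.numeric(priors), length(priors) > 0L, !is.null(names(priors)))
  for (p in names(cpt)) {
    spec <- predictors[[p]]
    if (is.null(spec)) stop("CPT for unknown predictor '", p, "'")
    m <- cpt[[p]]
    if (!is.matrix(m) || !identical(rownames(m), .classes) ||
        !identical(colnames(m), spec$levels)) {
      stop("CPT for '", p, "' must be a 2 x ", length(spec$levels),
           " matrix with rows cardiac/noncardiac and the registry levels")
    }
    if (any(m < 0) || any(m > 1)) {
      stop("CPT for '", p, "' has probabilities outside [0, 1]")
    }
    if (any(abs(rowSums(m) - 1) > 1e-12)) {
      stop("CPT rows for '", p, "' do not sum to 1")
    }
  }
  if (any(priors <= 0) || any(priors >= 1)) {
    stop("priors must lie strictly in (0, 1)")
  }
  structure(
    list(predictors = predictors[names(cpt)], cpt = cpt, priors = priors),
    class = "syncope_cpts"
  )
}

#' @export
print.syncope_cpts <- function(x, digits = 3, ...) {
  cat("Conditional probability tables for", length(x$cpt), "predictor(s)\n")
  cat("Priors P(cardiac):",
      paste(names(x$priors), round(x$priors, digits), sep = "=",
            collapse = ", "), "\n")
  for (p in names(x$cpt)) {
    cat("\n", p, ":\n", sep = "")
    print(round(x$cpt[[p]], digits))
  }
  invisible(x)
}

#' Derive conditional probability tables from pooled counts
#'
#' Converts pooled literature counts to maximum-likelihood conditional
#' probabilities: \eqn{P(\mathrm{level} \mid \mathrm{class})} is the pooled
#' cell count divided by the pooled class total. No smoothing or
#' pseudocounts are applied — the tables report raw pooled frequencies, and
#' zero cells are legal (they propagate as genuine zeros at prediction
#' time).
#'
#' @param pooled a list of `pooled_table`s (one per predictor), e.g. built
#'   with [pool_counts()].
#' @param priors named numeric vector of P(cardiac) per population.
#' @inheritParams syncope_cpts
#' @return A [syncope_cpts] object.
#' @examples
#' counts <- syncope_fixture_counts()
#' pooled <- list(nausea = pool_counts(counts, "nausea"))
#' derive_cpts(pooled, priors = c(calgary = 138 / 663))
#' @export
derive_cpts <- function(pooled, priors, predictors = syncope_predictors()) {
  stopifnot(is.list(pooled), length(pooled) > 0L)
  cpt <- lapply(pooled, function(pt) {
    stopifnot(inherits(pt, "pooled_table"))
    if (any(pt$row_totals == 0)) {
      stop("degenerate pooled table for '", pt$predictor$name,
           "': a class total is zero")
    }
    sweep(pt$counts, 1L, pt$row_totals, "/")
  })
  names(cpt) <- vapply(pooled, function(pt) pt$predictor$name, character(1))
  syncope_cpts(cpt, priors, predictors)
}

#' Fit the literature-based cardiac syncope model
#'
#' Fits the naive Bayes (joint Bernoulli) model of cardiac syncope from a
#' long-format table of per-study predictor-by-diagnosis counts:
#'
#' 1. pools each candidate predictor's counts across studies
#'    ([pool_counts()]),
#' 2. computes the pooled association statistics ([chi_square()],
#'    [likelihood_ratio()]),
#' 3. applies the selection rule — significant in >= `min_studies` source
#'    studies *and* pooled p < `alpha` — when per-study significance
#'    metadata is supplied ([select_predictors()]), and
#' 4. converts the retained pooled tables to conditional probability
#'    tables ([derive_cpts()]) alongside the population priors.
#'
#' With the bundled fixtures and default settings this retains the ten
#' predictors of the published model (palpitations is the candidate
#' excluded on pooled significance, p = 0.06).
#'
#' @param counts long count table (columns `study_id, predictor, class,
#'   level, count`); default the bundled derivation fixture.
#' @param priors named numeric vector of P(cardiac) per population; default
#'   the bundled test-population priors.
#' @param significance per-study significance metadata (columns
#'   `predictor`, `study_id`), or `NULL` to skip rule (i); default the
#'   bundled (synthetic) significance fixture.
#' @param min_studies,alpha selection thresholds; defaults 3 and 0.05.
#' @param predictors predictor registry.
#' @return An object of class `syncope_model` with components
#'   `association` (per-candidate statistics), `retained`, `excluded`,
#'   `pooled` (pooled tables of retained predictors), `cpts`
#'   ([syncope_cpts]) and `priors`. Supports `print()`, `summary()`,
#'   `coef()`, `predict()` and `simulate()`.
#' @examples
#' fit <- syncope_model()
#' fit
#' coef(fit)[coef(fit)$predictor == "nausea", ]
#' @export
syncope_model <- function(counts = syncope_fixture_counts(),
                          priors = syncope_fixture_priors(),
                          significance = syncope_fixture_significance(),
                          min_studies = 3, alpha = 0.05,
                          predictors = syncope_predictors()) {
  counts <- validate_count_table(counts, predictors)
  assoc <- association_table(counts, predictors)
  retained <- if (is.null(significance)) {
    assoc$predictor
  } else {
    select_predictors(assoc, significance, min_studies, alpha)
  }
  if (length(retained) == 0L) stop("no predictor passes the selection rule")
  pooled <- lapply(retained, pool_counts, counts = counts,
                   predictors = predictors)
  names(pooled) <- retained
  cpts <- derive_cpts(pooled, priors, predictors)
  structure(
    list(
      association = assoc,
      retained = retained,
      excluded = setdiff(assoc$predictor, retained),
      pooled = pooled,
      cpts = cpts,
      priors = priors,
      call = match.call()
    ),
    class = "syncope_model"
  )
}

#' @export
print.syncope_model <- function(x, ...) {
  cat("Literature-based naive Bayes model of cardiac syncope\n")
  cat("Retained predictors (", length(x$retained), "): ",
      paste(x$retained, collapse = ", "), "\n", sep = "")
  if (length(x$excluded) > 0L) {
    cat("Excluded candidates: ", paste(x$excluded, collapse = ", "),
        "\n", sep = "")
  }
  cat("Populations: ",
      paste(names(x$priors), sprintf("%.1f%%", 100 * x$priors), sep = " ",
            collapse = ", "), " (prior P(cardiac))\n", sep = "")
  invisible(x)
}

#' @export
summary.syncope_model <- function(object, ...) {
  out <- object$association
  out$retained <- out$predictor %in% object$retained
  class(out) <- c("summary.syncope_model", "data.frame")
  out
}

#' @export
print.summary.syncope_model <- function(x, ...) {
  cat("Pooled association with cardiac vs. non-cardiac syncope\n\n")
  y <- as.data.frame(x)
  y$chi2 <- round(y$chi2, 1)
  y$p_value <- signif(y$p_value, 2)
  y$likelihood_ratio <- round(y$likelihood_ratio, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.syncope_model <- function(object, ...) {
  rows <- lapply(names(object$cpts$cpt), function(p) {
    m <- object$cpts$cpt[[p]]
    expand <- expand.grid(class = rownames(m), level = colnames(m),
                          stringsAsFactors = FALSE)
    data.frame(predictor = p, expand,
               probability = m[cbind(expand$class, expand$level)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
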