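#' Describe a patient population for cohort simulation
#'
#' A population spec is everything the generator needs for one centre: the
#' cohort size, the prior prevalence of cardiac syncope, the
#' class-conditional level distribution of each collected predictor, which
#' predictors the centre collects at all (`observed`), and the
#' patient-level missingness rate per predictor.
#'
#' @param name population identifier.
#' @param n cohort size.
#' @param prior P(cardiac) in (0, 1).
#' @param class_conditional named list of 2 x K probability matrices (rows
#'   `cardiac`/`noncardiac`, columns the predictor levels), one per
#'   collected predictor.
#' @param observed character vector of collected predictors; default all
#'   predictors in `class_conditional`.
#' @param missing_rate named numeric vector of per-predictor probabilities
#'   that an individual patient's value is missing; predictors not named
#'   default to 0.
#' @param spells_proxy flag that the spells variable is generated under a
#'   proxy coding ("one spell" vs. "more than one", mapped onto the
#'   model's le2/gt2 levels), as in the Milan centre.
#' @param predictors predictor registry.
#' @return An object of class `population_spec`.
#' @seealso [table3_population_specs()], [generate_cohort()]
#' @export
population_spec <- function(name, n, prior, class_conditional,
                            observed = names(class_conditional),
                            missing_rate = numeric(0),
                            spells_proxy = FALSE,
                            predictors = syncope_predictors()) {
  stopifnot(is.character(name), length(name) == 1L, n >= 1L,
            prior > 0, prior < 1, is.list(class_conditional))
  if (!all(observed %in% names(class_conditional))) {
    stop("observed predictors must all have class-conditional tables")
  }
  for (p in names(class_conditional)) {
    spec <- predictors[[p]]
    if (is.null(spec)) stop("unknown predictor '", p, "'")
    m <- class_conditional[[p]]
    if (!is.matrix(m) || !identical(rownames(m), .classes) ||
        !identical(colnames(m), spec$levels)) {
      stop("class-conditional table for '", p,
           "' must have rows cardiac/noncardiac and the registry levels")
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
      stop("class-conditional rows for '", p, "' must each sum to 1")
    }
  }
  mr <- stats::setNames(rep(0, length(observed)), observed)
  mr[names(missing_rate)[names(missing_rate) %in% observed]] <-
    missing_rate[names(missing_rate) %in% observed]
  if (any(mr < 0 | mr > 1)) stop("missing rates must lie in [0, 1]")
  structure(
    list(name = name, n = as.integer(n), prior = prior,
         class_conditional = class_conditional, observed = observed,
         missing_rate = mr, spells_proxy = isTRUE(spells_proxy)),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population> ", x$name, ": n = ", x$n,
      ", prior P(cardiac) = ", round(x$prior, 4),
      "\n  collected: ", paste(x$observed, collapse = ", "), "\n", sep = "")
  if (x$spells_proxy) {
    cat("  note: spells generated under the one-vs-more proxy coding\n")
  }
  invisible(x)
}

#' Population specs of the four test centres
#'
#' Builds [population_spec]s for the Calgary, Amsterdam, Milan and
#' Rochester test populations from the bundled distribution fixtures
#' (exact counts, so the specs are rounding-free). Per-predictor
#' missingness is the observed shortfall of a predictor's counts against
#' the population size. Milan's spells variable carries the
#' one-vs-more-than-one proxy flag, and blurred vision in Rochester —
#' extracted from free text rather than asked — is excluded from the
#' collected set unless `include_rochester_blurred_vision = TRUE`.
#'
#' @param populations which centres to build; default all four.
#' @param include_rochester_blurred_vision include the free-text blurred
#'   vision variable in the Rochester spec; default `FALSE`.
#' @param predictors predictor registry.
#' @return Named list of [population_spec] objects.
#' @examples
#' specs <- table3_population_specs()
#' specs$calgary
#' @export
table3_population_specs <- function(populations = NULL,
                                    include_rochester_blurred_vision = FALSE,
                                    predictors = syncope_predictors()) {
  counts <- syncope_fixture_populations()
  sizes <- syncope_fixture_sizes()
  if (is.null(populations)) populations <- sizes$population
  specs <- lapply(populations, function(g) {
    sz <- sizes[sizes$population == g, ]
    if (nrow(sz) != 1L) stop("unknown population '", g, "'")
    n_total <- sz$cardiac_n + sz$noncardiac_n
    x <- counts[counts$population == g, ]
    observed <- unique(x$predictor)
    if (g == "rochester" && !include_rochester_blurred_vision) {
      observed <- setdiff(observed, "blurred_vision")
    }
    cc <- list()
    mr <- numeric(0)
    for (p in observed) {
      spec <- predictors[[p]]
      m <- matrix(0, 2L, length(spec$levels),
                  dimnames = list(.classes, spec$levels))
      xp <- x[x$predictor == p, ]
      m[cbind(xp$class, xp$level)] <- xp$count
      mr[p] <- 1 - sum(m) / n_total
      cc[[p]] <- sweep(m, 1L, rowSums(m), "/")
    }
    population_spec(g, n = n_total, prior = sz$cardiac_n / n_total,
                    class_conditional = cc, observed = observed,
                    missing_rate = pmax(mr, 0),
                    spells_proxy = (g == "milan"),
                    predictors = predictors)
  })
  stats::setNames(specs, populations)
}

#' Simulate a multi-centre patient cohort
#'
#' Draws `spec$n` patients: the true class from the population prior, then
#' each collected predictor independently from its class-conditional level
#' distribution (the data-generating process the diagnostic model assumes),
#' then patient-level missingness independently of class. Predictors the
#' centre does not collect are entirely `NA`. The draw is deterministic
#' given `seed`.
#'
#' @param spec a [population_spec].
#' @param seed integer seed.
#' @param n optional cohort-size override.
#' @param predictors predictor registry; columns are emitted for every
#'   registry predictor so cohorts from different centres row-bind cleanly.
#' @return `data.frame` with columns `population`, `true_class`, and one
#'   character column per registry predictor (`NA` = missing).
#' @examples
#' spec <- table3_population_specs("calgary")$calgary
#' cohort <- generate_cohort(spec, seed = 1, n = 100)
#' table(cohort$true_class)
#' @export
generate_cohort <- function(spec, seed, n = NULL,
                            predictors = syncope_predictors()) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(n)) n <- spec$n
  set.seed(seed)
  cls <- ifelse(stats::runif(n) < spec$prior, "cardiac", "noncardiac")
  out <- data.frame(population = rep(spec$name, n), true_class = cls,
                    stringsAsFactors = FALSE)
  for (p in names(predictors)) {
    v <- rep(NA_character_, n)
    if (p %in% spec$observed) {
      m <- spec$class_conditional[[p]]
      lv <- colnames(m)
      for (k in .classes) {
        i <- which(cls == k)
        if (length(i) > 0L) {
          v[i] <- lv[sample.int(length(lv), length(i), replace = TRUE,
                                prob = m[k, ])]
        }
      }
      miss <- spec$missing_rate[[p]]
      if (miss > 0) v[stats::runif(n) < miss] <- NA_character_
    }
    out[[p]] <- v
  }
  out
}

#' Recover conditional probability tables from a labelled cohort
#'
#' Maximum-likelihood estimation on a cohort with known true classes:
#' each CPT entry is the observed class-conditional relative frequency over
#' non-missing values, and the prior is the observed cardiac fraction.
#' Used as the parameter-recovery harness for the generator, and to fit
#' centre-specific tables from (synthetic) patient-level data.
#'
#' @param cohort `data.frame` with `true_class` plus predictor columns;
#'   both classes must be present.
#' @param predictors which predictors to fit; default every registry
#'   predictor with at least one observed value per class.
#' @param registry predictor registry.
#' @return A [syncope_cpts] with a single prior named after the cohort's
#'   population (or `"cohort"` when absent or mixed).
#' @export
fit_cpts_from_cohort <- function(cohort, predictors = NULL,
                                 registry = syncope_predictors()) {
  stopifnot(is.data.frame(cohort), "true_class" %in% names(cohort))
  cls <- as.character(cohort$true_class)
  if (length(unique(cls[cls %in% .classes])) < 2L) {
    stop("degenerate cohort: both classes must be present")
  }
  if (is.null(predictors)) {
    predictors <- intersect(names(registry), names(cohort))
  }
  cpt <- list()
  for (p in predictors) {
    spec <- registry[[p]]
    v <- as.character(cohort[[p]])
    obs <- !is.na(v) & nzchar(v)
    m <- matrix(0, 2L, length(spec$levels),
                dimnames = list(.classes, spec$levels))
    ok <- TRUE
    for (k in .classes) {
      i <- obs & cls == k
      if (!any(i)) { ok <- FALSE; break }
      tab <- table(factor(v[i], levels = spec$levels))
      m[k, ] <- as.numeric(tab) / sum(tab)
    }
    if (ok) cpt[[p]] <- m
  }
  if (length(cpt) == 0L) stop("no predictor has observations in both classes")
  pop <- unique(as.character(cohort$population))
  prior_name <- if (length(pop) == 1L) pop else "cohort"
  syncope_cpts(cpt, stats::setNames(mean(cls == "cardiac"), prior_name),
               registry)
}

#' Simulate cohorts from a fitted model
#'
#' Draws synthetic cohorts whose data-generating process is exactly the
#' fitted model: the requested population's prior and the model's pooled
#' conditional probability tables, with every modelled predictor collected
#' and no missingness.
#'
#' @param object a [syncope_model].
#' @param nsim number of cohorts; default 1.
#' @param seed integer seed (replicate `i` uses `seed + i - 1`).
#' @param population which model population's prior to use.
#' @param n cohort size; default 1000.
#' @param ... unused.
#' @return A single cohort `data.frame` if `nsim = 1`, else a list of them.
#' @export
simulate.syncope_model <- function(object, nsim = 1, seed = 1,
                                   population = names(object$priors)[1L],
                                   n = 1000, ...) {
  stopifnot(population %in% names(object$priors))
  spec <- population_spec(
    name = population, n = n, prior = unname(object$priors[population]),
    class_conditional = object$cpts$cpt
  )
  sims <- lapply(seq_len(nsim), function(i) {
    generate_cohort(spec, seed = seed + i - 1L)
  })
  if (nsim == 1L) sims[[1L]] else sims
}
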