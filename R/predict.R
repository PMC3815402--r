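#' Posterior probability of cardiac syncope for a patient cohort
#'
#' For each patient the prior prevalence of cardiac syncope in their
#' population is updated by the class-conditional probabilities of the
#' observed predictor values:
#' \deqn{p = \frac{\pi \prod_j P(x_j \mid \mathrm{cardiac})}
#'                {\pi \prod_j P(x_j \mid \mathrm{cardiac}) +
#'                 (1-\pi) \prod_j P(x_j \mid \mathrm{noncardiac})}}
#' with the product over the *observed, non-missing* predictors in the
#' requested subset. Missing values (and predictors a centre never
#' collected) are marginalized by omission, which is exact under the
#' model's conditional-independence assumption: a patient with no observed
#' predictors scores exactly the prior. Products are accumulated in log
#' space; zero conditional probabilities propagate as genuine zeros, and a
#' patient whose observed values have probability zero under *both* classes
#' raises an error rather than returning 0/0.
#'
#' @param cohort `data.frame` with a `population` column and one column per
#'   predictor holding level labels (`NA` or `""` = missing).
#' @param cpts a [syncope_cpts] parameter set.
#' @param predictors optional character vector restricting the product to a
#'   subset of the modelled predictors (e.g.
#'   [parsimonious_predictors()]); default all modelled predictors.
#' @param cutoff posterior classification cutoff in (0, 1); default 0.02,
#'   chosen to favour sensitivity over specificity. A posterior exactly at
#'   the cutoff is classified cardiac.
#' @return A `data.frame` with one row per patient: `posterior`, `label`
#'   (`"cardiac"`/`"noncardiac"` at the cutoff), `prior`, and `n_used`
#'   (number of non-missing predictors entering the product).
#' @examples
#' cpts <- derive_cpts(
#'   list(nausea = pool_counts(syncope_fixture_counts(), "nausea")),
#'   priors = c(calgary = 0.21)
#' )
#' cohort <- data.frame(population = "calgary", nausea = "yes")
#' posterior_probability(cohort, cpts)
#' @export
posterior_probability <- function(cohort, cpts, predictors = NULL,
                                  cutoff = 0.02) {
  stopifnot(inherits(cpts, "syncope_cpts"), is.data.frame(cohort))
  if (!"population" %in% names(cohort)) {
    stop("cohort needs a 'population' column")
  }
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must lie in (0, 1)")
  if (is.null(predictors)) {
    predictors <- names(cpts$cpt)
  } else {
    unknown <- setdiff(predictors, names(cpts$cpt))
    if (length(unknown) > 0L) {
      stop("predictor(s) not in the model: ", paste(unknown, collapse = ", "))
    }
  }
  pop <- as.character(cohort$population)
  unknown <- setdiff(unique(pop), names(cpts$priors))
  if (length(unknown) > 0L) {
    stop("no prior for population(s): ", paste(unknown, collapse = ", "))
  }
  prior <- unname(cpts$priors[pop])

  n <- nrow(cohort)
  ll1 <- ll0 <- numeric(n)   # log-likelihood accumulators per class
  n_used <- integer(n)
  for (p in intersect(predictors, names(cohort))) {
    spec <- cpts$predictors[[p]]
    v <- as.character(cohort[[p]])
    obs <- !is.na(v) & nzchar(v)
    if (!all(v[obs] %in% spec$levels)) {
      stop("illegal level '", setdiff(v[obs], spec$levels)[1L],
           "' for predictor '", p, "'")
    }
    idx <- match(v[obs], spec$levels)
    m <- cpts$cpt[[p]]
    ll1[obs] <- ll1[obs] + log(m["cardiac", ][idx])
    ll0[obs] <- ll0[obs] + log(m["noncardiac", ][idx])
    n_used[obs] <- n_used[obs] + 1L
  }
  a <- log(prior) + ll1
  b <- log1p(-prior) + ll0
  dead <- which(is.infinite(a) & is.infinite(b) & a < 0 & b < 0)
  if (length(dead) > 0L) {
    stop("undefined posterior for patient(s) ",
         paste(utils::head(dead, 5L), collapse = ", "),
         ": observed values have probability zero under both classes")
  }
  posterior <- 1 / (1 + exp(b - a))
  data.frame(
    posterior = posterior,
    label = classify(posterior, cutoff),
    prior = prior,
    n_used = n_used,
    stringsAsFactors = FALSE
  )
}

#' Classify a posterior probability at a cutoff
#'
#' Labels a posterior as `"cardiac"` when it is greater than *or equal to*
#' the cutoff (the tie goes to cardiac, the sensitivity-favouring
#' convention) and `"noncardiac"` otherwise.
#'
#' @param posterior numeric vector of posterior probabilities.
#' @param cutoff classification cutoff in (0, 1); default 0.02.
#' @return Character vector of labels.
#' @examples
#' classify(c(0.001, 0.02, 0.4))
#' @export
classify <- function(posterior, cutoff = 0.02) {
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must lie in (0, 1)")
  ifelse(posterior >= cutoff, "cardiac", "noncardiac")
}

#' Predict posterior probabilities from a fitted model
#'
#' @param object a [syncope_model].
#' @param newdata patient cohort `data.frame` (a `population` column plus
#'   one column per predictor; `NA`/empty = missing).
#' @param type `"response"` for the numeric posterior vector, `"class"` for
#'   labels at the cutoff, `"detail"` for the full per-patient data frame
#'   of [posterior_probability()].
#' @param variant `"full"` (all retained predictors), `"parsimonious"` (the
#'   5 predictors collected by every centre), or `"custom"` together with
#'   `predictors`.
#' @param predictors custom predictor subset when `variant = "custom"`.
#' @param cutoff classification cutoff; default 0.02.
#' @param ... unused.
#' @return See `type`.
#' @examples
#' fit <- syncope_model()
#' pt <- data.frame(population = "calgary", age = "ge60", gender = "male",
#'                  structural_heart_disease = "yes", spells = "le2",
#'                  prodrome = "no")
#' predict(fit, pt, variant = "parsimonious")
#' @export
predict.syncope_model <- function(object, newdata,
                                  type = c("response", "class", "detail"),
                                  variant = c("full", "parsimonious",
                                              "custom"),
                                  predictors = NULL, cutoff = 0.02, ...) {
  type <- match.arg(type)
  variant <- match.arg(variant)
  subset <- switch(variant,
    full = object$retained,
    parsimonious = intersect(object$retained, parsimonious_predictors()),
    custom = {
      if (is.null(predictors)) stop("variant = 'custom' needs `predictors`")
      predictors
    }
  )
  res <- posterior_probability(newdata, object$cpts, subset, cutoff)
  switch(type,
    response = res$posterior,
    class = res$label,
    detail = res
  )
}
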