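#' Read and write patient cohorts
#'
#' Cohort files are UTF-8 comma-separated with a header row: one row per
#' patient, a `population` column, optionally `true_class`, and one column
#' per predictor with string level labels. Missing values are encoded as
#' empty fields and read back as `NA`.
#'
#' @param path file path.
#' @param cohort cohort `data.frame`.
#' @return `read_cohort()`: a `data.frame`. `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", na.strings = "")
  if (!"population" %in% names(x)) {
    stop(path, ": cohort file needs a 'population' column")
  }
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read and write conditional probability table files
#'
#' CPT sets are serialized as JSON: the population priors plus, per
#' predictor, the ordered levels, the cardiac-pointing level and the two
#' class-conditional probability rows at full double precision, so a
#' written file reads back to an equal [syncope_cpts].
#'
#' @param cpts a [syncope_cpts].
#' @param path file path.
#' @param predictors predictor registry used to re-validate on read.
#' @return `read_cpts()`: a [syncope_cpts]. `write_cpts()`: `path`,
#'   invisibly.
#' @export
write_cpts <- function(cpts, path) {
  stopifnot(inherits(cpts, "syncope_cpts"))
  obj <- list(
    priors = as.list(cpts$priors),
    predictors = lapply(names(cpts$cpt), function(p) {
      m <- cpts$cpt[[p]]
      list(name = p,
           levels = colnames(m),
           cardiac_level = cpts$predictors[[p]]$cardiac_level,
           p_cardiac = unname(m["cardiac", ]),
           p_noncardiac = unname(m["noncardiac", ]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cpts
#' @export
read_cpts <- function(path, predictors = syncope_predictors()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cpt <- list()
  for (pr in obj$predictors) {
    m <- rbind(cardiac = as.numeric(pr$p_cardiac),
               noncardiac = as.numeric(pr$p_noncardiac))
    colnames(m) <- pr$levels
    cpt[[pr$name]] <- m
  }
  priors <- unlist(obj$priors)
  syncope_cpts(cpt, priors, predictors)
}

#' Write a prediction table
#'
#' One row per patient: identifier, population, posterior, label at the
#' cutoff, number of predictors used, and the true class when known.
#'
#' @param predictions the `detail` data frame from
#'   [posterior_probability()] / `predict(..., type = "detail")`.
#' @param cohort the cohort the predictions refer to (for `population`,
#'   `true_class`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, cohort, path) {
  out <- data.frame(
    patient = seq_len(nrow(predictions)),
    population = cohort$population,
    posterior = predictions$posterior,
    label = predictions$label,
    n_used = predictions$n_used,
    stringsAsFactors = FALSE
  )
  if ("true_class" %in% names(cohort)) out$true_class <- cohort$true_class
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  x$posterior <- as.numeric(x$posterior)
  x
}

#' Read and write resampling plans
#'
#' Plans are stored as structured config, JSON or YAML by file extension
#' (`.json` vs `.yaml`/`.yml`): the stratum table with target proportions,
#' the number of replicates, the replicate size and the seed.
#'
#' @param plan a [resample_plan].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_resample_plan()`: a [resample_plan].
#'   `write_resample_plan()`: `path`, invisibly.
#' @export
write_resample_plan <- function(plan, path) {
  stopifnot(inherits(plan, "resample_plan"))
  obj <- list(
    strata = plan$targets,
    n_replicates = plan$n_replicates,
    replicate_size = plan$replicate_size,
    seed = plan$seed
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    obj$strata <- lapply(seq_len(nrow(plan$targets)),
                         function(i) as.list(plan$targets[i, ]))
    yaml::write_yaml(obj, path, precision = 15L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_resample_plan
#' @export
read_resample_plan <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  strata <- do.call(rbind, lapply(obj$strata, function(s) {
    as.data.frame(s, stringsAsFactors = FALSE)
  }))
  strata$proportion <- as.numeric(strata$proportion)
  size <- obj$replicate_size
  if (length(size) == 0L) size <- NULL   # JSON null round-trips as empty
  resample_plan(strata,
                n_replicates = obj$n_replicates,
                replicate_size = size,
                seed = obj$seed)
}
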