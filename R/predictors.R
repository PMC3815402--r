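#' Clinical history predictors of cardiac syncope
#'
#' The model works on a fixed vocabulary of categorical history and
#' demographic predictors. Each predictor has 2 or 3 ordered levels and a
#' designated *cardiac-pointing* level: the level whose observation raises
#' the probability of a cardiac cause (presence of supine or effort syncope,
#' male sex, few spells; *absence* of the autonomic prodrome symptoms
#' nausea, diaphoresis, blurred vision).
#'
#' `syncope_predictors()` returns the registry of candidate predictors,
#' including palpitations (a candidate that the pooled evidence does not
#' retain). `parsimonious_predictors()` returns the 5-variable subset
#' collected by every test centre: age, gender, structural heart disease,
#' number of spells, and prodrome.
#'
#' @param names optional character vector restricting the registry to the
#'   named predictors (in registry order).
#' @return For `syncope_predictors()`, a list of `predictor_spec` objects
#'   keyed by predictor name. For `parsimonious_predictors()`, a character
#'   vector of 5 predictor names.
#' @examples
#' names(syncope_predictors())
#' parsimonious_predictors()
#' @export
syncope_predictors <- function(names = NULL) {
  reg <- list(
    predictor_spec("age", c("lt40", "40to60", "ge60"), "ge60"),
    predictor_spec("gender", c("male", "female"), "male"),
    predictor_spec("structural_heart_disease", c("yes", "no"), "yes"),
    predictor_spec("spells", c("le2", "gt2"), "le2"),
    predictor_spec("nausea", c("yes", "no"), "no"),
    predictor_spec("diaphoresis", c("yes", "no"), "no"),
    predictor_spec("prodrome", c("yes", "no"), "no"),
    predictor_spec("blurred_vision", c("yes", "no"), "no"),
    predictor_spec("palpitations", c("yes", "no"), "no"),
    predictor_spec("supine_syncope", c("yes", "no"), "yes"),
    predictor_spec("effort_syncope", c("yes", "no"), "yes")
  )
  names(reg) <- vapply(reg, function(p) p$name, character(1))
  if (!is.null(names)) {
    unknown <- setdiff(names, base::names(reg))
    if (length(unknown) > 0L) {
      stop("unknown predictor(s): ", paste(unknown, collapse = ", "))
    }
    reg <- reg[base::names(reg) %in% names]
  }
  reg
}

#' @rdname syncope_predictors
#' @export
parsimonious_predictors <- function() {
  c("age", "gender", "structural_heart_disease", "spells", "prodrome")
}

#' Define a categorical predictor
#'
#' @param name predictor identifier.
#' @param levels ordered character vector of 2 or 3 unique level labels.
#' @param cardiac_level the level pointing toward cardiac syncope; must be
#'   one of `levels`.
#' @return An object of class `predictor_spec`.
#' @examples
#' predictor_spec("gender", c("male", "female"), "male")
#' @export
predictor_spec <- function(name, levels, cardiac_level) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L || length(levels) > 3L) {
    stop("predictor '", name, "': need 2 or 3 levels, got ", length(levels))
  }
  if (anyDuplicated(levels)) {
    stop("predictor '", name, "': duplicated level labels")
  }
  if (!cardiac_level %in% levels) {
    stop("predictor '", name, "': cardiac_level '", cardiac_level,
         "' is not a level")
  }
  structure(
    list(name = name, levels = levels, cardiac_level = cardiac_level),
    class = "predictor_spec"
  )
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat("<predictor> ", x$name, ": ", paste(x$levels, collapse = " / "),
      "  (cardiac-pointing: ", x$cardiac_level, ")\n", sep = "")
  invisible(x)
}

# the two diagnosis classes, in row order used throughout
.classes <- c("cardiac", "noncardiac")
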