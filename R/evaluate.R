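#' Concordance (c-statistic) of predicted probabilities
#'
#' The c-statistic is the probability that a randomly chosen cardiac
#' patient receives a higher score than a randomly chosen non-cardiac
#' patient, with ties counted one half — equivalently the area under the
#' empirical ROC curve. It is computed from midranks, which is identical to
#' exhaustive pair counting with the half-tie convention and gives the
#' exact identity \eqn{U = c \cdot n_1 n_0} with the Mann-Whitney U
#' statistic.
#'
#' @param scores numeric vector of predicted probabilities (any monotone
#'   score works; the statistic is rank-based).
#' @param labels vector with the true classes; `positive` identifies the
#'   cardiac label.
#' @param positive label value of the positive (cardiac) class; default
#'   `"cardiac"`.
#' @return A single number in `[0, 1]`.
#' @examples
#' c_statistic(c(0.9, 0.8, 0.8, 0.1),
#'             c("cardiac", "cardiac", "noncardiac", "noncardiac"))
#' @export
c_statistic <- function(scores, labels, positive = "cardiac") {
  stopifnot(length(scores) == length(labels), is.numeric(scores),
            !anyNA(scores), !anyNA(labels))
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("c-statistic undefined: both classes must be present")
  }
  r <- rank(scores)   # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Sensitivity is the fraction of cardiac patients with score at or above
#' the cutoff (the at-cutoff tie counts as a positive call, matching
#' [classify()]); specificity is the fraction of non-cardiac patients
#' below it.
#'
#' @inheritParams c_statistic
#' @param cutoff decision cutoff; default 0.02.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @examples
#' sens_spec_at(c(0.5, 0.01, 0.3, 0.001),
#'              c("cardiac", "cardiac", "noncardiac", "noncardiac"))
#' @export
sens_spec_at <- function(scores, labels, cutoff = 0.02,
                         positive = "cardiac") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop("sensitivity/specificity undefined: both classes must be present")
  }
  c(sensitivity = mean(scores[pos] >= cutoff),
    specificity = mean(scores[!pos] < cutoff))
}

#' Empirical ROC curve
#'
#' Thresholds are taken at the unique observed scores, descending, with a
#' `+Inf` sentinel, so the curve runs from (0, 0) to (1, 1); a score at or
#' above the threshold is called positive. The trapezoidal area under the
#' resulting curve equals [c_statistic()].
#'
#' @inheritParams c_statistic
#' @return An object of class `syncope_roc`: a list with `thresholds`,
#'   `sensitivity`, `one_minus_specificity` and `c_statistic`; supports
#'   `print()` and `plot()`.
#' @examples
#' roc <- roc_curve(c(0.9, 0.8, 0.8, 0.1),
#'                  c("cardiac", "cardiac", "noncardiac", "noncardiac"))
#' roc$c_statistic
#' @export
roc_curve <- function(scores, labels, positive = "cardiac") {
  cstat <- c_statistic(scores, labels, positive)  # also validates input
  pos <- labels == positive
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  structure(
    list(thresholds = thr, sensitivity = sens,
         one_minus_specificity = fpr, c_statistic = cstat),
    class = "syncope_roc"
  )
}

#' @export
print.syncope_roc <- function(x, ...) {
  cat("ROC curve:", length(x$thresholds), "thresholds, c-statistic =",
      round(x$c_statistic, 3), "\n")
  invisible(x)
}

#' @param x a `syncope_roc` object.
#' @param ... passed to [graphics::plot()].
#' @rdname roc_curve
#' @export
plot.syncope_roc <- function(x, ...) {
  graphics::plot(x$one_minus_specificity, x$sensitivity, type = "l",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("c = %.3f", x$c_statistic))
  invisible(x)
}

#' Mann-Whitney rank-sum comparison of two score groups
#'
#' Two-sided Mann-Whitney test that cardiac and non-cardiac patients
#' receive the same score distribution, using the normal approximation
#' with tie correction (no continuity correction). The returned U statistic
#' counts pairs where the first group wins, ties half, so
#' `U == c_statistic * n1 * n0`.
#'
#' @param scores_cardiac,scores_noncardiac numeric score vectors for the
#'   two groups (both non-empty).
#' @return List with `statistic` (U) and `p_value`.
#' @examples
#' rank_sum_test(c(0.8, 0.9), c(0.1, 0.2))
#' @export
rank_sum_test <- function(scores_cardiac, scores_noncardiac) {
  stopifnot(length(scores_cardiac) > 0L, length(scores_noncardiac) > 0L)
  wt <- stats::wilcox.test(scores_cardiac, scores_noncardiac,
                           alternative = "two.sided",
                           exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-population performance report
#'
#' Convenience wrapper evaluating predicted posteriors against true classes
#' within each population: c-statistic, sensitivity and specificity at the
#' cutoff, and the rank-sum p-value comparing cardiac vs. non-cardiac
#' scores.
#'
#' @param scores numeric posterior vector.
#' @param labels true classes (`"cardiac"`/`"noncardiac"`).
#' @param population population label per patient (a single label is
#'   recycled).
#' @param cutoff decision cutoff; default 0.02.
#' @return `data.frame` with one row per population.
#' @export
evaluate_predictions <- function(scores, labels, population = "all",
                                 cutoff = 0.02) {
  population <- rep_len(as.character(population), length(scores))
  rows <- lapply(unique(population), function(g) {
    i <- population == g
    ss <- sens_spec_at(scores[i], labels[i], cutoff)
    rs <- rank_sum_test(scores[i][labels[i] == "cardiac"],
                        scores[i][labels[i] != "cardiac"])
    data.frame(population = g, n = sum(i),
               c_statistic = c_statistic(scores[i], labels[i]),
               sensitivity = unname(ss["sensitivity"]),
               specificity = unname(ss["specificity"]),
               rank_sum_p = rs$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
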