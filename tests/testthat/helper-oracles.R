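# Independent oracles and tiny builders used across the suite.

# Pearson chi-square by direct sum((O - E)^2 / E)
chi2_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Concordance by exhaustive pair counting, ties half
auc_oracle <- function(scores, labels, positive = "cardiac") {
  s1 <- scores[labels == positive]
  s0 <- scores[labels != positive]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Posterior by brute-force enumeration of the joint model over a complete
# assignment: prior * product of CPT entries per class, then normalize.
# Plain products, no log space.
joint_posterior_oracle <- function(assignment, cpts, population) {
  pr <- cpts$priors[[population]]
  j <- c(cardiac = pr, noncardiac = 1 - pr)
  for (p in names(assignment)) {
    m <- cpts$cpt[[p]]
    j <- j * m[, assignment[[p]]]
  }
  unname(j["cardiac"] / sum(j))
}

# Minimal two-predictor CPT set for hand-checked examples
tiny_cpts <- function(prior = 0.21) {
  syncope_cpts(
    cpt = list(
      nausea = rbind(cardiac = c(yes = 0.08, no = 0.92),
                     noncardiac = c(yes = 0.20, no = 0.80)),
      gender = rbind(cardiac = c(male = 0.64, female = 0.36),
                     noncardiac = c(male = 0.49, female = 0.51))
    ),
    priors = c(testpop = prior)
  )
}

# Random 2 x k count table with all margins positive
random_table <- function(k = 2) {
  repeat {
    m <- matrix(rpois(2 * k, lambda = 8) + 1L, nrow = 2,
                dimnames = list(c("cardiac", "noncardiac"),
                                paste0("l", seq_len(k))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Long count-table rows for one study/predictor from a named count list
count_rows <- function(study, predictor, cardiac, noncardiac) {
  rbind(
    data.frame(study_id = study, predictor = predictor, class = "cardiac",
               level = names(cardiac), count = unname(cardiac),
               stringsAsFactors = FALSE),
    data.frame(study_id = study, predictor = predictor, class = "noncardiac",
               level = names(noncardiac), count = unname(noncardiac),
               stringsAsFactors = FALSE)
  )
}
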