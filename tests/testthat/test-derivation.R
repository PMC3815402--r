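counts <- syncope_fixture_counts()

test_that("pooling sums per-study cells and is order-independent", {
  supine <- pool_counts(counts, "supine_syncope")
  expect_equal(supine$counts["cardiac", "yes"], 17L)   # 9 + 2 + 6
  expect_equal(supine$counts["noncardiac", "yes"], 12L)
  expect_equal(supine$row_totals, c(cardiac = 170L, noncardiac = 507L))

  effort <- pool_counts(counts, "effort_syncope")
  expect_equal(effort$counts["cardiac", "yes"], 16L)   # 10 + 6
  expect_equal(effort$grand_total, 597L)

  # a single study pools to itself
  one <- counts[counts$study_id == "alboni" &
                counts$predictor == "supine_syncope", ]
  single <- pool_counts(one)
  expect_equal(single$counts["cardiac", ], c(yes = 9L, no = 69L))

  # permuting the input rows changes nothing
  set.seed(1)
  for (p in c("gender", "age", "prodrome")) {
    shuffled <- counts[sample.int(nrow(counts)), ]
    expect_identical(pool_counts(shuffled, p)$counts,
                     pool_counts(counts, p)$counts)
  }

  # row/col/grand totals are consistent with the cells
  for (p in unique(counts$predictor)) {
    pt <- pool_counts(counts, p)
    expect_identical(pt$row_totals, rowSums(pt$counts))
    expect_identical(pt$col_totals, colSums(pt$counts))
    expect_identical(pt$grand_total, sum(pt$counts))
  }
})

test_that("pooling rejects misaligned or malformed tables", {
  bad <- counts
  bad$level[bad$predictor == "gender"][1] <- "unknown_level"
  expect_error(pool_counts(bad, "gender"), "outside its registry levels")
  neg <- counts
  neg$count[1] <- -1L
  expect_error(pool_counts(neg, "age"), "negative")
  expect_error(pool_counts(counts, "not_a_predictor"), "unknown predictor")
})

test_that("chi-square matches a brute-force oracle and flags degeneracy", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:3, 1)
    p <- if (k == 2) "gender" else "age"
    lv <- syncope_predictors()[[p]]$levels
    m <- random_table(k)
    long <- data.frame(study_id = "s1", predictor = p,
                       class = rep(c("cardiac", "noncardiac"), each = k),
                       level = rep(lv, 2), count = c(m[1, ], m[2, ]),
                       stringsAsFactors = FALSE)
    pt <- pool_counts(long)
    a <- chi_square(pt)
    expect_equal(a$chi2, chi2_oracle(pt$counts), tolerance = 1e-9)
    expect_equal(a$df, k - 1L)
  }

  # identical row proportions give exactly zero association
  flat <- pool_counts(count_rows("s", "gender", c(male = 10, female = 30),
                                 c(male = 20, female = 60)))
  expect_equal(chi_square(flat)$chi2, 0)
  expect_equal(chi_square(flat)$p_value, 1)

  degen <- pool_counts(count_rows("s", "gender", c(male = 10, female = 0),
                                  c(male = 20, female = 0)))
  expect_error(chi_square(degen), "degenerate")
})

test_that("likelihood ratios come from exact pooled counts", {
  expect_equal(likelihood_ratio(pool_counts(counts, "effort_syncope")),
               (16 / 122) / (9 / 475))
  expect_equal(likelihood_ratio(pool_counts(counts, "supine_syncope")),
               (17 / 170) / (12 / 507))

  # equal class-conditional proportions give exactly 1
  flat <- pool_counts(count_rows("s", "gender", c(male = 30, female = 10),
                                 c(male = 60, female = 20)))
  expect_equal(likelihood_ratio(flat), 1)

  # LR(level) * P(level | noncardiac) = P(level | cardiac), exactly
  for (p in c("gender", "spells", "nausea", "supine_syncope")) {
    pt <- pool_counts(counts, p)
    lev <- pt$predictor$cardiac_level
    lr <- likelihood_ratio(pt, lev)
    p0 <- pt$counts["noncardiac", lev] / pt$row_totals["noncardiac"]
    p1 <- pt$counts["cardiac", lev] / pt$row_totals["cardiac"]
    expect_equal(unname(lr * p0), unname(p1))
  }

  expect_error(likelihood_ratio(pool_counts(counts, "age")),
               "binary")
  zero <- pool_counts(count_rows("s", "supine_syncope",
                                 c(yes = 3, no = 7), c(yes = 0, no = 10)))
  expect_error(likelihood_ratio(zero, "yes"), "undefined")
})

test_that("age-bin reconstruction follows the normal CDF and sums to n", {
  expect_identical(counts_from_mean_sd(100, 50, 10, c(40, 60)),
                   c(16L, 68L, 16L))   # pnorm at +/- 1 sd, rounded
  expect_identical(counts_from_mean_sd(10, 30, 1, c(40, 60)),
                   c(10L, 0L, 0L))
  # sd = 0 concentrates in the bin containing the mean; 60 is in the
  # upper bin by the documented edge convention
  expect_identical(counts_from_mean_sd(7, 50, 0, c(40, 60)), c(0L, 7L, 0L))
  expect_identical(counts_from_mean_sd(7, 60, 0, c(40, 60)), c(0L, 0L, 7L))
  expect_identical(counts_from_mean_sd(7, 40, 0, c(40, 60)), c(0L, 7L, 0L))

  set.seed(7)
  for (i in 1:30) {
    n <- sample(1:500, 1)
    cnt <- counts_from_mean_sd(n, runif(1, 20, 90), runif(1, 0, 30),
                               c(40, 60))
    expect_equal(sum(cnt), n)
    expect_true(all(cnt >= 0))
  }
  expect_error(counts_from_mean_sd(10, 50, 10, c(60, 40)))
})

test_that("the selection rule keeps the ten published predictors", {
  assoc <- association_table(counts)
  sig <- syncope_fixture_significance()
  kept <- select_predictors(assoc, sig)

  expect_length(kept, 10)
  expect_false("palpitations" %in% kept)   # pooled p = 0.06
  expect_gt(assoc$p_value[assoc$predictor == "palpitations"], 0.05)
  expect_setequal(kept, setdiff(names(syncope_predictors()), "palpitations"))

  # a predictor significant in fewer than min_studies sources is dropped
  # even when the pooled association is strong
  sig2 <- sig[!(sig$predictor == "gender" & sig$study_id == "iglesias"), ]
  expect_false("gender" %in% select_predictors(assoc, sig2))
  expect_true("gender" %in% select_predictors(assoc, sig2, min_studies = 2))
})

test_that("conditional probability tables are pooled relative frequencies", {
  pooled <- lapply(c("nausea", "gender", "age"), pool_counts,
                   counts = counts)
  names(pooled) <- c("nausea", "gender", "age")
  cpts <- derive_cpts(pooled, priors = c(calgary = 138 / 663))

  expect_equal(cpts$cpt$nausea["cardiac", "yes"], 34 / 424)
  expect_equal(round(cpts$cpt$nausea["cardiac", "yes"], 2), 0.08)
  expect_equal(cpts$cpt$nausea["noncardiac", "yes"], 307 / 1552)
  expect_equal(round(cpts$cpt$nausea["noncardiac", "yes"], 2), 0.20)

  for (m in cpts$cpt) {
    expect_equal(unname(rowSums(m)), c(1, 1), tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
  }

  # a level never seen in either class gets probability 1 elsewhere
  onecol <- pool_counts(count_rows("s", "gender", c(male = 5, female = 0),
                                   c(male = 9, female = 0)))
  cp <- derive_cpts(list(gender = onecol), c(pop = 0.1))
  expect_equal(unname(cp$cpt$gender[, "male"]), c(1, 1))

  empty <- pool_counts(count_rows("s", "gender", c(male = 0, female = 0),
                                  c(male = 9, female = 1)))
  expect_error(derive_cpts(list(gender = empty), c(pop = 0.1)),
               "degenerate")
})
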