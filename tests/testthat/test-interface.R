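test_that("every file the package writes reads back to an equal value", {
  tmp <- withr::local_tempdir()

  # CPT set: JSON round trip at full double precision
  fit <- syncope_model()
  cpt_file <- file.path(tmp, "cpts.json")
  write_cpts(fit$cpts, cpt_file)
  back <- read_cpts(cpt_file)
  expect_equal(back$cpt, fit$cpts$cpt)
  expect_equal(back$priors, fit$cpts$priors)

  # cohort CSV round trip, empty field = missing
  spec <- table3_population_specs("milan")$milan
  cohort <- generate_cohort(spec, seed = 9, n = 40)
  co_file <- file.path(tmp, "cohort.csv")
  write_cohort(cohort, co_file)
  back_co <- read_cohort(co_file)
  expect_equal(back_co, cohort)

  # resampling plan: JSON and YAML round trips
  plan <- default_resample_plan(n_replicates = 7, replicate_size = 50,
                                seed = 42)
  for (f in c("plan.json", "plan.yaml")) {
    p_file <- file.path(tmp, f)
    write_resample_plan(plan, p_file)
    back_plan <- read_resample_plan(p_file)
    expect_equal(back_plan$targets$proportion, plan$targets$proportion)
    expect_equal(back_plan$n_replicates, plan$n_replicates)
    expect_equal(back_plan$replicate_size, plan$replicate_size)
    expect_equal(back_plan$seed, plan$seed)
  }

  # predictions CSV
  pred <- predict(fit, cohort, type = "detail")
  pr_file <- file.path(tmp, "pred.csv")
  write_predictions(pred, cohort, pr_file)
  back_pred <- read_predictions(pr_file)
  expect_equal(back_pred$posterior, pred$posterior)
  expect_equal(back_pred$true_class, cohort$true_class)
})

test_that("the derive subcommand reproduces the published report", {
  tmp <- withr::local_tempdir()
  expect_message(syncope_cli(c("derive", "--out-dir", tmp)),
                 "retained 10 predictor")
  report <- utils::read.csv(file.path(tmp, "association_report.csv"))
  expect_equal(report$chi2[report$predictor == "gender"], 25.4)
  expect_equal(report$likelihood_ratio[report$predictor == "gender"], 1.30)
  cpts <- read_cpts(file.path(tmp, "cpts.json"))
  expect_length(cpts$cpt, 10)   # tables for the retained predictors only

  # malformed input: row-level diagnostics, error raised
  bad <- file.path(tmp, "bad.csv")
  writeLines(c("study_id,predictor,class,level,count",
               "s1,gender,cardiac,male,notanumber"), bad)
  expect_error(syncope_cli(c("derive", "--counts", bad)), "row")
  empty <- file.path(tmp, "empty.csv")
  writeLines("study_id,predictor,class,level,count", empty)
  expect_error(syncope_cli(c("derive", "--counts", empty)), "empty")
})

test_that("usage errors are raised for unknown or incomplete commands", {
  expect_error(syncope_cli(character(0)), "usage")
  expect_error(syncope_cli("frobnicate"), "usage")
  expect_error(syncope_cli("predict"), "--cohort")
  expect_error(syncope_cli("evaluate"), "--predictions")
})

test_that("predict subcommand scores cohorts and logs the subset", {
  tmp <- withr::local_tempdir()
  fit <- syncope_model()
  cpt_file <- file.path(tmp, "cpts.json")
  write_cpts(fit$cpts, cpt_file)

  cohort <- simulate(fit, seed = 21, population = "calgary", n = 60)
  # one patient with everything missing scores exactly the prior
  cohort[1, names(fit$cpts$cpt)] <- NA
  co_file <- file.path(tmp, "cohort.csv")
  write_cohort(cohort, co_file)
  out <- file.path(tmp, "pred.csv")

  expect_message(
    syncope_cli(c("predict", "--cohort", co_file, "--cpts", cpt_file,
                  "--variant", "parsimonious", "--out", out)),
    "with 5 predictor")
  pred <- read_predictions(out)
  expect_equal(pred$posterior[1], 138 / 663, tolerance = 1e-12)

  # deterministic: scoring twice gives identical files
  out2 <- file.path(tmp, "pred2.csv")
  suppressMessages(
    syncope_cli(c("predict", "--cohort", co_file, "--cpts", cpt_file,
                  "--variant", "parsimonious", "--out", out2)))
  expect_identical(readLines(out), readLines(out2))
})

test_that("simulate-predict-evaluate-resample runs end to end", {
  tmp <- withr::local_tempdir()
  co_file <- file.path(tmp, "cohort.csv")
  cpt_dir <- file.path(tmp, "derived")
  pred_file <- file.path(tmp, "pred.csv")
  metr_file <- file.path(tmp, "metrics.csv")
  rs_file <- file.path(tmp, "resample.csv")

  suppressMessages({
    syncope_cli(c("simulate", "--n", "400", "--seed", "19",
                  "--out", co_file))
    syncope_cli(c("derive", "--out-dir", cpt_dir))
    syncope_cli(c("predict", "--cohort", co_file,
                  "--cpts", file.path(cpt_dir, "cpts.json"),
                  "--out", pred_file))
    syncope_cli(c("evaluate", "--predictions", pred_file,
                  "--out", metr_file))
    syncope_cli(c("resample", "--predictions", pred_file,
                  "--cohort", co_file, "--replicates", "50",
                  "--seed", "4", "--out", rs_file))
  })

  metrics <- utils::read.csv(metr_file)
  expect_setequal(metrics$population,
                  c("calgary", "amsterdam", "milan", "rochester"))
  expect_true(all(metrics$c_statistic > 0.5))

  rs <- utils::read.csv(rs_file)
  expect_equal(rs$n_replicates, 50)
  expect_equal(rs$seed, 4)
  expect_true(rs$mean > 0.5 && rs$mean < 1)

  # single-class input surfaces a clear evaluation error
  pred <- read_predictions(pred_file)
  pred$true_class <- "cardiac"
  one_file <- file.path(tmp, "oneclass.csv")
  utils::write.csv(pred, one_file, row.names = FALSE, na = "")
  expect_error(
    syncope_cli(c("evaluate", "--predictions", one_file)), "both classes")

  # infeasible plan surfaced through the CLI
  plan <- resample_plan(
    data.frame(age = "lt40", spells = "le2", proportion = 1),
    n_replicates = 5, seed = 1)
  cohort <- read_cohort(co_file)
  cohort$age <- "ge60"
  co2 <- file.path(tmp, "cohort2.csv")
  write_cohort(cohort, co2)
  plan_file <- file.path(tmp, "plan.json")
  write_resample_plan(plan, plan_file)
  expect_error(
    syncope_cli(c("resample", "--predictions", pred_file, "--cohort", co2,
                  "--plan", plan_file)), "infeasible")
})
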