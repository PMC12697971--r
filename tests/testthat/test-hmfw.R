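spec_small <- synthetic_spec(n_samples = 40, n_features = 250, n_informative = 8,
                             n_redundant_per_informative = 2,
                             class_separation = 2.5, seed = 61)

test_that("a full run is deterministic under its master seed", {
  ds <- generate_synthetic_omics(spec_small)
  ctl <- small_control(iterations = 6)
  f1 <- hmfw(ds, control = ctl, seed = 19)
  f2 <- hmfw(ds, control = ctl, seed = 19)
  expect_identical(f1$feature_indices, f2$feature_indices)
  expect_identical(f1$best$acc_mean, f2$best$acc_mean)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$restarts, f2$restarts)
  expect_identical(f1$digest, f2$digest)
  f3 <- hmfw(ds, control = ctl, seed = 20)
  expect_false(identical(f1$trace$best_acc, f3$trace$best_acc) &&
                 identical(f1$feature_indices, f3$feature_indices))
})

test_that("run-level invariants: contraction, monotone best, restart accounting, schedule", {
  ds <- generate_synthetic_omics(spec_small)
  fit <- hmfw(ds, control = small_control(iterations = 12), seed = 23)
  # selection is a contraction through the pre-screen
  expect_true(all(fit$feature_indices %in% fit$f1$feature))
  expect_lte(fit$best$subset_length, nrow(fit$f1))
  # best-so-far accuracy never decreases, including across restarts
  expect_true(all(diff(fit$trace$best_acc) >= 0))
  # one filter execution per restart plus the initial one
  expect_equal(fit$filter_execs, fit$restarts + 1L)
  # CAD returns to zero on every restart iteration
  expect_true(all(fit$trace$cad[fit$trace$restart] == 0L))
  # the global relevance/redundancy schedule stays on the unit circle
  expect_equal(fit$trace$s^2 + fit$trace$y^2, rep(1, nrow(fit$trace)))
  expect_true(all(diff(fit$trace$s) <= 0))
})

test_that("model methods expose the selection, predictions and traces", {
  ds <- generate_synthetic_omics(spec_small)
  fit <- hmfw(ds, control = small_control(iterations = 5), seed = 29)
  cf <- coef(fit)
  expect_named(cf)
  expect_identical(unname(cf), fit$feature_indices)
  expect_identical(names(cf), fit$feature_ids)

  pred <- predict(fit, ds$matrix)
  expect_s3_class(pred, "factor")
  expect_length(pred, 40)
  expect_gte(mean(pred == ds$labels), 0.9)  # refit on all data, separable signal

  expect_output(print(fit), "HMF-W feature selection")
  expect_output(print(summary(fit)), "config digest")
  pf <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pf)
  expect_silent(plot(fit))
  grDevices::dev.off()
})

test_that("repeated runs aggregate exactly and reproduce byte-identical CSVs", {
  ds <- generate_synthetic_omics(
    synthetic_spec(n_samples = 30, n_features = 120, n_informative = 5,
                   n_redundant_per_informative = 1, class_separation = 3,
                   seed = 71))
  ctl <- small_control(iterations = 4, population = 6)
  runs <- hmfw_repeat(ds, control = ctl, runs = 2, master_seed = 5)
  expect_equal(runs$acc_mean,
               mean(sapply(runs$fits, function(f) f$best$acc_mean)),
               tolerance = 1e-12)
  expect_equal(runs$summary$seed, c(5L, 6L))

  c1 <- withr::local_tempfile(fileext = ".csv")
  c2 <- withr::local_tempfile(fileext = ".csv")
  write_aggregate_csv(runs, c1)
  runs2 <- hmfw_repeat(ds, control = ctl, runs = 2, master_seed = 5)
  write_aggregate_csv(runs2, c2)
  expect_identical(readLines(c1), readLines(c2))

  jf <- withr::local_tempfile(fileext = ".json")
  write_run_report(runs$fits[[1]], jf, dataset = "synthetic")
  rep <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(rep$config_digest, runs$fits[[1]]$digest)
  expect_equal(rep$restarts, runs$fits[[1]]$restarts)
  expect_equal(rep$best$LEN, runs$fits[[1]]$best$subset_length)
  expect_equal(rep$seeds$master, 5)
})

test_that("simulation writes a CSV plus a faithful planted-feature sidecar", {
  spec <- synthetic_spec(n_samples = 15, n_features = 30, n_informative = 4,
                         n_redundant_per_informative = 1, seed = 13)
  out <- withr::local_tempfile(fileext = ".csv")
  files <- simulate_omics(spec, out)
  lines <- readLines(out)
  expect_length(lines, 16)  # header + n_samples rows
  expect_length(strsplit(lines[1], ",")[[1]], 31)  # features + label column
  side <- jsonlite::read_json(files$sidecar, simplifyVector = TRUE)
  expect_length(side$informative, 4)
  expect_length(side$redundant, 4)
  expect_equal(side$spec$seed, 13)
  # planted indices point at the planted ids
  ds <- load_expression_table(out, "class")
  expect_true(all(grepl("^inf", ds$feature_ids[side$informative])))
  expect_true(all(grepl("^red", ds$feature_ids[side$redundant])))

  before <- readLines(out)
  simulate_omics(spec, out)
  expect_identical(readLines(out), before)
})

test_that("recovery metrics score a selection against the planted truth", {
  planted <- list(informative = c(2, 5), redundant = c(7, 9),
                  spec = list(n_features = 20))
  exact <- recovery_eval(c(2, 5, 7, 9), planted)
  expect_equal(exact$precision, 1)
  expect_equal(exact$recall, 1)
  noise <- recovery_eval(c(1, 3, 4), planted)
  expect_equal(noise$precision, 0)
  expect_equal(noise$recall, 0)
  expect_equal(noise$base_rate, 4 / 20)
  empty <- recovery_eval(integer(0), planted)
  expect_equal(empty$precision, 0)
})

test_that("the experiment driver writes per-run reports and an aggregate", {
  spec <- synthetic_spec(n_samples = 24, n_features = 80, n_informative = 4,
                         n_redundant_per_informative = 1, class_separation = 3,
                         seed = 91)
  csv <- withr::local_tempfile(fileext = ".csv")
  simulate_omics(spec, csv)
  out_dir <- withr::local_tempdir()
  res <- run_experiment(csv, "class", control = small_control(iterations = 3,
                                                              population = 6),
                        runs = 2, master_seed = 3, out_dir = out_dir)
  expect_s3_class(res, "hmfw_runs")
  expect_true(file.exists(file.path(out_dir, "run_001.json")))
  expect_true(file.exists(file.path(out_dir, "run_002.json")))
  expect_true(file.exists(file.path(out_dir, "aggregate.csv")))
  agg <- read.csv(file.path(out_dir, "aggregate.csv"))
  expect_equal(nrow(agg), 3)  # two runs + mean row
})
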