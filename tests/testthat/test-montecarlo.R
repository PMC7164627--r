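test_that("false-positive rate is the proportion preferring too many classes", {
  expect_equal(false_positive_rate(c(1, 1, 2, 1)), 0.25)
  expect_equal(false_positive_rate(rep(1, 10)), 0)
  expect_equal(false_positive_rate(rep(2, 5)), 1)
  expect_error(false_positive_rate(integer(0)), "no decisions")
})

test_that("run_cell is reproducible and keeps honest denominators", {
  cell <- design_cell(0, 0, 60, "normal", replications = 4, base_seed = 123)
  pol <- start_policy(4, 6, 1)
  r1 <- run_cell(cell, starts = pol)
  r2 <- run_cell(cell, starts = pol)
  expect_identical(r1$reps, r2$reps)
  expect_lte(r1$fpr_denominator, cell$replications)
  expect_equal(r1$fpr_denominator,
               sum(r1$reps$converged1 & r1$reps$converged2))
  expect_true(all(r1$fpr >= 0 & r1$fpr <= 1, na.rm = TRUE))
  # fpr consistency with the recorded per-replication indices
  joint <- r1$reps$converged1 & r1$reps$converged2
  expect_equal(r1$fpr[["bic"]],
               mean(r1$reps$bic2[joint] < r1$reps$bic1[joint]))
})

test_that("tabulate produces tidy tables that round-trip through CSV", {
  empty <- tabulate_results(list())
  expect_equal(nrow(empty$fpr), 0)
  expect_true(all(c("skew", "n", "family", "criterion", "fpr", "denominator")
                  %in% names(empty$fpr)))

  cell <- design_cell(1, 2, 60, "normal", replications = 3, base_seed = 7)
  res <- run_cell(cell, starts = start_policy(3, 5, 1))
  tabs <- tabulate_results(list(res))
  expect_equal(nrow(tabs$fpr), 6)          # one row per criterion
  expect_equal(nrow(tabs$convergence), 2)  # one row per class count
  expect_equal(unique(tabs$fpr$n), 60L)

  dir <- withr::local_tempdir()
  write_results_tables(tabs, dir)
  back <- read_results_tables(dir)
  expect_equal(back$fpr$fpr, tabs$fpr$fpr)
  expect_equal(back$convergence$mean_bic, tabs$convergence$mean_bic)
})

test_that("run_study consumes a config (list or YAML) and runs the grid", {
  cfg <- list(conditions = list(c(0, 0)), ns = 50, families = "normal",
              replications = 2, base_seed = 99, n_random_starts = 3)
  out <- run_study(cfg)
  expect_length(out$results, 1)
  expect_equal(out$tables$convergence$family, rep("normal", 2))

  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  out2 <- run_study(path)
  expect_equal(out2$tables$fpr$fpr, out$tables$fpr$fpr)
})
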