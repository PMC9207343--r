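test_that("identical groups show no direction and near-unit rank-sum p-values", {
  set.seed(121)
  tbl <- null_complexity_table(10, "g", function(n) rnorm(n))
  res <- compare_groups(tbl, tbl, design = "simulated")
  expect_identical(nrow(res), 9L)
  expect_true(all(res$direction == "none"))
  expect_true(all(res$p_raw > 0.9))
  expect_true(all(res$test == "wilcoxon-ranksum"))
})

test_that("real-design comparisons use Student's t and record Shapiro-Wilk", {
  set.seed(131)
  a <- null_complexity_table(15, "a", function(n) rnorm(n))
  b <- null_complexity_table(13, "b", function(n) rnorm(n, mean = 2))
  res <- compare_groups(a, b, design = "real",
                        group_names = c("patient", "control"))
  expect_true(all(res$test == "students-t"))
  expect_true(all(is.finite(res$shapiro_a) & is.finite(res$shapiro_b)))
  expect_true(all(c("mean_patient", "mean_control") %in% names(res)))
  expect_true(all(res$direction == "A<B"))
})

test_that("FDR adjustment is monotone and never below the raw p-value", {
  set.seed(141)
  a <- null_complexity_table(12, "a", function(n) rnorm(n))
  b <- null_complexity_table(12, "b", function(n) rnorm(n, mean = 0.3))
  res <- compare_groups(a, b, design = "simulated")
  expect_true(all(res$p_fdr >= res$p_raw - 1e-15))
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_fdr[ord]) >= -1e-15))
})

test_that("group comparison rejects undersized or mismatched inputs", {
  set.seed(151)
  small <- null_complexity_table(2, "s", function(n) rnorm(n))
  ok <- null_complexity_table(10, "g", function(n) rnorm(n))
  expect_error(compare_groups(small, ok), ">= 3 units")
  missing_cell <- ok[!(ok$region == "central" & ok$measure == "HFD"), ]
  expect_error(compare_groups(missing_cell, ok), "cells")
})

test_that("type-I error of the cell tests sits near the nominal level", {
  # scaled-down null calibration; the acceptance suite runs 1,000 replicates
  set.seed(161)
  hits <- replicate(200, {
    a <- null_complexity_table(15, "a", function(n) rnorm(n))
    b <- null_complexity_table(13, "b", function(n) rnorm(n))
    mean(compare_groups(a, b, design = "real")$p_raw < 0.05)
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("injected group shifts are recovered with the right direction", {
  set.seed(171)
  correct <- replicate(200, {
    a <- null_complexity_table(15, "a", function(n) rnorm(n, mean = 2, sd = 1))
    b <- null_complexity_table(13, "b", function(n) rnorm(n, mean = 0, sd = 1))
    res <- compare_groups(a, b, design = "real")
    mean(res$direction == "A>B")
  })
  expect_gte(mean(correct), 0.95)
})

test_that("two-group ANOVA equals the squared pooled-variance t statistic", {
  set.seed(181)
  real <- null_complexity_table(15, "r", function(n) rnorm(n))
  sim <- null_complexity_table(15, "s", function(n) rnorm(n, mean = 0.5))
  av <- real_vs_simulated_anova(real, sim)
  expect_identical(nrow(av), 3L)
  for (m in av$measure) {
    tt <- t.test(real$value[real$measure == m], sim$value[sim$measure == m],
                 var.equal = TRUE)
    row <- av[av$measure == m, ]
    expect_equal(row$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(row$p, tt$p.value, tolerance = 1e-9)
  }
  # identical groups: F ~ 0, p ~ 1
  av0 <- real_vs_simulated_anova(real, real)
  expect_true(all(av0$F < 1e-20))
  expect_true(all(av0$p > 1 - 1e-10))
  # separated groups: overwhelming evidence
  far <- null_complexity_table(15, "f", function(n) rnorm(n, mean = 50, sd = 0.1))
  expect_true(all(real_vs_simulated_anova(real, far)$p < 1e-6))
  expect_error(real_vs_simulated_anova(real[0, ], sim), "non-empty")
})

test_that("the full synthetic study runs end to end, deterministically", {
  cfg <- study_config(n_control = 4, n_patient = 4, duration = 4,
                      n_runs = 4, seed = 7)
  rep1 <- run_full_study(cfg, verbose = FALSE)
  expect_length(rep1$comparisons, 3)
  for (cmp in rep1$comparisons) expect_identical(nrow(cmp), 9L)
  expect_identical(nrow(rep1$anova), 3L)
  # lesioning the control matrix lowers its mean strength
  expect_lt(rep1$mean_strengths[["lesion"]], rep1$mean_strengths[["control"]])
  # determinism: identical seed, identical statistics
  rep2 <- run_full_study(cfg, verbose = FALSE)
  expect_identical(rep1$mean_strengths, rep2$mean_strengths)
  for (nm in names(rep1$comparisons)) {
    expect_identical(rep1$comparisons[[nm]]$p_raw, rep2$comparisons[[nm]]$p_raw)
  }
  expect_identical(rep1$anova, rep2$anova)
  # report writer produces the expected artifacts
  dir <- tempfile("study")
  write_study_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "matrix_control.csv")))
  expect_true(file.exists(file.path(dir, "comparison_sim_lesion_vs_control.csv")))
  expect_true(file.exists(file.path(dir, "summary.txt")))
  unlink(dir, recursive = TRUE)
})

test_that("EEG CSV round trip preserves the data", {
  set.seed(191)
  rec <- eeg_recording(matrix(rnorm(500 * 3), 500, 3), fs = 400,
                       channel_labels = c("Fz", "Cz", "Pz"))
  path <- tempfile(fileext = ".csv")
  write_eeg_csv(rec, path)
  rec2 <- read_eeg_csv(path, fs = 400)
  expect_equal(rec2$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rec2$channel_labels, rec$channel_labels)
  unlink(path)
})

test_that("region map partitions the montage into the three scalp regions", {
  map <- region_map()
  expect_length(map, 21)
  expect_identical(sum(map == "anterior"), 7L)
  expect_identical(sum(map == "central"), 5L)
  expect_identical(sum(map == "posterior"), 7L)
  expect_setequal(names(map)[map == "unassigned"], c("T1", "T2"))
  expect_setequal(region_channels("central"), c("T3", "C3", "Cz", "C4", "T4"))
})
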