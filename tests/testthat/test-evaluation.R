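test_that("subject filter implements the three exclusion rules", {
  res <- tibble::tibble(
    subject_id = c("a", "b", "c", "d", "e"),
    ac_full = c(0.40, 0.80, 0.80, 0.80, 0.50),
    ac_small = c(0.60, 0.85, 0.70, 0.49, 0.45))
  kept <- filter_subjects(res)
  expect_identical(kept$subject_id, "c")
  # boundary: equality small == full is retained
  res2 <- tibble::tibble(subject_id = "x", ac_full = 0.7, ac_small = 0.7)
  expect_equal(nrow(filter_subjects(res2)), 1)
})

test_that("paired test matches the closed-form t statistic", {
  d <- c(0.01, 0.02, 0.03, 0.02, 0.02)
  base <- c(0.70, 0.72, 0.68, 0.74, 0.71)
  out <- paired_improvement_test(base, base + d)
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$mean_delta, mean(d))
  expect_equal(out$p_value, 2 * stats::pt(-abs(tstat), df = 4),
               tolerance = 1e-12)
  # degenerate all-zero differences
  same <- paired_improvement_test(base, base)
  expect_equal(same$mean_delta, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry
  rev <- paired_improvement_test(base + d, base)
  expect_equal(rev$mean_delta, -out$mean_delta)
  expect_equal(rev$p_value, out$p_value)
  expect_error(paired_improvement_test(base, d[1:3]), "LengthMismatch")
})

test_that("proficiency grid search finds the discriminating threshold", {
  set.seed(71)
  # below 0.67 the strategy is pure noise; above it adds a clear gain
  ac_small <- c(runif(6, 0.55, 0.64), runif(6, 0.70, 0.90))
  delta <- c(rnorm(6, 0, 0.05), rnorm(6, 0.03, 0.004))
  res <- tibble::tibble(subject_id = as.character(1:12),
                        ac_small = ac_small,
                        ac_strat = ac_small + delta)
  th <- proficiency_grid_search(res, "ac_strat",
                                thresholds = c(0.5, 0.67, 0.8))
  expect_equal(as.numeric(th), 0.67)
  # a strategy significant everywhere ties; the lowest threshold wins
  res2 <- res; res2$ac_strat <- res2$ac_small + 0.05
  th2 <- proficiency_grid_search(res2, "ac_strat",
                                 thresholds = c(0.5, 0.67))
  expect_equal(as.numeric(th2), 0.5)
  expect_error(proficiency_grid_search(res, "ac_strat", numeric(0)))
  expect_error(proficiency_grid_search(res, "ac_strat", 0.99),
               "NoSubjectsAboveThreshold")
})

test_that("separable data reach perfect accuracy in both protocols", {
  # band-limited tone whose amplitude differs 4x between conditions:
  # the projected total power separates the classes with a wide margin
  set.seed(90)
  n_ep <- 21; n_ch <- 6; n <- 625; fs <- 250
  tt <- (0:(n - 1)) / fs
  pattern <- exp(-((1:n_ch) - 3)^2 / 4)
  data <- array(rnorm(2 * n_ep * n_ch * n, sd = 0.05), c(2 * n_ep, n_ch, n))
  amps <- rep(c(2, 0.5), each = n_ep)
  for (i in seq_len(2 * n_ep)) {
    tone <- amps[i] * sin(2 * pi * 12 * tt + runif(1, 0, 2 * pi))
    data[i, , ] <- data[i, , ] + outer(pattern, tone)
  }
  e <- epoch_set(data, fs, rep(c("L", "R"), each = n_ep))
  cfg <- mi_config("TP")
  expect_equal(as.numeric(inverse_cv(e, cfg, k = 3, seed = 1)), 1.0)
  expect_equal(as.numeric(full_cv(e, cfg, k = 7, seed = 1)), 1.0)
})

test_that("inverse and regular protocols coincide at two folds", {
  spec <- small_cohort_spec(noise = 1.5, n_epochs = 12)
  e <- make_subject(spec, 1)
  cfg <- mi_config("TP")
  expect_equal(as.numeric(inverse_cv(e, cfg, k = 2, seed = 42)),
               as.numeric(full_cv(e, cfg, k = 2, seed = 42)))
})

test_that("cross-validation audits the fold partition and leakage", {
  spec <- small_cohort_spec(noise = 1, n_epochs = 18)
  e <- make_subject(spec, 1)
  cfg <- mi_config("TP")
  acc <- inverse_cv(e, cfg, strategy_noise(factor = 1), k = 3, seed = 2)
  audit <- attr(acc, "audit")
  expect_length(audit, 3)
  all_train <- integer(0)
  for (fold in audit) {
    expect_length(intersect(fold$train_idx, fold$val_idx), 0)
    expect_setequal(c(fold$train_idx, fold$val_idx), seq_len(36))
    # training grew by factor * size: 6 real + 6 synthetic rows per class
    expect_equal(fold$n_train_rows, 2 * length(fold$train_idx))
    all_train <- c(all_train, fold$train_idx)
  }
  # every epoch trains exactly once across the three rotations
  expect_setequal(all_train, seq_len(36))
  expect_equal(anyDuplicated(all_train), 0)
})

test_that("augmentation factor zero reproduces the baseline exactly", {
  spec <- small_cohort_spec(noise = 1.2, n_epochs = 12)
  e <- make_subject(spec, 1)
  cfg <- mi_config("TP")
  base <- inverse_cv(e, cfg, NULL, k = 3, seed = 5)
  zero <- inverse_cv(e, cfg, strategy_noise(factor = 0), k = 3, seed = 5)
  expect_identical(as.numeric(base), as.numeric(zero))
})

test_that("label-shuffled data classify at chance level", {
  spec <- small_cohort_spec(noise = 0.8, n_epochs = 15)
  e <- make_subject(spec, 1)
  cfg <- mi_config("TP")
  accs <- vapply(1:25, function(s) {
    es <- e
    es$labels <- withr::with_seed(1000 + s, sample(e$labels))
    as.numeric(inverse_cv(es, cfg, k = 3, seed = s))
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.07)
})

test_that("the cohort benchmark aggregates into the report shape", {
  spec <- small_cohort_spec(noise = 1)
  spec$n_subjects <- 4
  spec$sensor_noise_sd <- 1
  spec$noise_spread <- c(0.5, 2)
  subs <- make_cohort(spec, 4)
  bm <- run_benchmark(subs, list(strategy_noise(factor = 1)),
                      mi_config("TP"), seed = 3)
  expect_s3_class(bm, "mi_benchmark")
  expect_equal(nrow(bm$subject_results), 4)
  expect_true(all(c("ac_full", "ac_small", "ac_noise_x1") %in%
                    names(bm$subject_results)))
  expect_true(all(unlist(bm$subject_results[-1]) >= 0 &
                    unlist(bm$subject_results[-1]) <= 1))
  expect_identical(tidy(bm), bm$report)
  expect_equal(glance(bm)$n_subjects, 4)
  expect_true(all(bm$retained %in% bm$subject_results$subject_id))
  # report deltas are consistent with the subject table
  kept <- bm$subject_results[bm$subject_results$subject_id %in% bm$retained, ]
  expect_equal(bm$report$delta_vs_small,
               mean(kept$ac_noise_x1 - kept$ac_small))
  # an empty strategy list still yields the baseline columns
  bm0 <- run_benchmark(subs, list(), mi_config("TP"), seed = 3)
  expect_equal(nrow(bm0$report), 0)
  expect_true(all(c("ac_full", "ac_small") %in% names(bm0$subject_results)))
})
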