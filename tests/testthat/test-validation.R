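test_that("the default design split reproduces the reference cell counts", {
  pm <- default_pm()
  plan <- make_classification_split(pm, seed = 1)
  expect_equal(plan$counts$calibration_complete, c(10, 10, 8))
  expect_equal(plan$counts$calibration_partial, c(2, 2, 4))
  expect_equal(plan$counts$validation_complete, c(2, 2, 1))
  expect_equal(plan$counts$validation_partial, c(1, 1, 2))
  # the four id sets are disjoint and cover the dataset
  ids <- c(plan$calibration_complete, plan$calibration_partial,
           plan$validation_complete, plan$validation_partial_external)
  expect_equal(sort(ids), sort(pm$sample_ids))
})

test_that("without partial samples the plan degenerates to plain MC CV", {
  des <- study_design(partial_counts = c(0, 0, 0))
  pm <- generate_dataset(des, season_effects(des, seed = 1), seed = 2)
  plan <- make_classification_split(pm, seed = 3)
  expect_length(plan$calibration_partial, 0)
  expect_length(plan$validation_partial_external, 0)
  expect_equal(length(plan$calibration_complete) +
                 length(plan$validation_complete), 33)
  des2 <- study_design(complete_counts = c(1, 5, 5))
  pm2 <- generate_dataset(des2, season_effects(des2, seed = 1), seed = 2)
  expect_error(make_classification_split(pm2, seed = 1), "fewer than 2")
})

test_that("calibration partial fraction stays in the protocol band over
           many seeds", {
  pm <- default_pm()
  fracs <- sapply(1:1000, function(s) {
    plan <- make_classification_split(pm, seed = s)
    n_cal_p <- length(plan$calibration_partial)
    n_cal <- n_cal_p + length(plan$calibration_complete)
    n_val_p <- length(plan$validation_partial_external)
    n_val <- n_val_p + length(plan$validation_complete)
    c(cal = n_cal_p / n_cal, val = n_val_p / n_val)
  })
  expect_true(all(fracs["cal", ] >= 0.15 & fracs["cal", ] <= 0.35))
  expect_true(all(fracs["val", ] >= 0.30 & fracs["val", ] <= 0.65))
})

test_that("elementary metrics match their definitions", {
  expect_equal(percent_correct(c("a", "b"), c("a", "b")), 100)
  expect_equal(percent_correct(c("a", "b", "a", "a"), c("a", "a", "a", "a")),
               75)
  expect_error(percent_correct(character(0), character(0)), "empty")
  expect_equal(rmse(c(3, 4)), sqrt(12.5))
  expect_error(rmse(numeric(0)), "empty")
  expect_equal(r_squared(rep(0, 5), rnorm(5) + 1), 1)
  # predicting by the calibration mean makes residuals equal the totals
  tot <- c(1.5, -2, 0.3)
  expect_equal(r_squared(tot, tot), 0)
  expect_error(r_squared(1, 0), "zero total")
})

test_that("classification validation is reproducible and internally
           consistent", {
  pm <- default_pm()
  run1 <- run_classification_validation(pm, "ppca_lda", orders = 2:3,
                                        n_iterations = 3, seed = 11)
  run2 <- run_classification_validation(pm, "ppca_lda", orders = 2:3,
                                        n_iterations = 3, seed = 11)
  expect_identical(run1$curve$per_iteration, run2$curve$per_iteration)
  expect_equal(run1$curve$mean_metric, rowMeans(run1$curve$per_iteration))
  expect_true(run1$curve$selected_order %in% run1$curve$orders)

  # the overall %CC is the sample-weighted mix of the two pools (9 = 5 + 4)
  mix <- (5 * run1$internal_curve$per_iteration +
            4 * run1$external_curve$per_iteration) / 9
  expect_equal(run1$curve$per_iteration, mix)

  run3 <- run_classification_validation(pm, "ppca_lda", orders = 2:3,
                                        n_iterations = 3, seed = 12)
  expect_false(identical(run1$curve$per_iteration, run3$curve$per_iteration))
})

test_that("external partial samples are never calibrated on in a full run", {
  pm <- default_pm()
  run <- run_classification_validation(pm, "plsda", orders = 2:3,
                                       n_iterations = 10, seed = 13)
  ext <- run$external_ids
  expect_length(ext, 4)  # 1 + 1 + 2 per month
  for (plan in run$splits) {
    cal <- c(plan$calibration_complete, plan$calibration_partial)
    expect_length(intersect(ext, cal), 0)
    expect_setequal(plan$validation_partial_external, ext)
  }
})

test_that("PLS-DA order sweep is capped by the mineral predictors", {
  pm <- default_pm()
  expect_error(run_classification_validation(pm, "plsda", orders = 1:9,
                                             n_iterations = 2, seed = 1),
               "mineral predictors")
  expect_error(run_imputation_validation(pm, "plsr", orders = 1:9,
                                         n_iterations = 2, seed = 1),
               "mineral predictors")
})

test_that("with FAME variables carrying most class signal, PPCA+LDA beats
           the mineral-only PLS-DA comparator (fixed seed)", {
  pm <- default_pm()
  ppca_run <- run_classification_validation(pm, "ppca_lda", orders = 1:8,
                                            n_iterations = 20, seed = 5)
  plsda_run <- run_classification_validation(pm, "plsda", orders = 1:8,
                                             n_iterations = 20, seed = 5)
  expect_gte(max(ppca_run$curve$mean_metric),
             max(plsda_run$curve$mean_metric))
})

test_that("imputation validation recovers a noiseless low-rank dataset", {
  des <- study_design()
  eff <- season_effects(des, q_true = 3, noise_sd = 1e-4, seed = 5)
  pm <- generate_dataset(des, eff, seed = 6)
  run <- run_imputation_validation(pm, "ppca", orders = 3, n_iterations = 5,
                                   seed = 7)
  expect_gt(run$r2$mean_metric, 99.9)
  expect_lt(run$rmsecv$mean_metric, 0.05)
})

test_that("PPCA imputation error at the generating order beats order 1", {
  pm <- default_pm()
  run <- run_imputation_validation(pm, "ppca", orders = c(1, 5),
                                   n_iterations = 10, seed = 8)
  expect_lt(run$rmsecv$mean_metric[2], run$rmsecv$mean_metric[1])
  expect_equal(run$rmsecv$selected_order, 5)
  # original-scale curves track the same ordering
  expect_lt(run$rmsecv_original$mean_metric[2],
            run$rmsecv_original$mean_metric[1])
})

test_that("PLSR and PPCA imputation run on the same protocol and agree on
           easy data", {
  des <- study_design()
  # strong mineral-FAME coupling: minerals nearly determine the latent state
  eff <- season_effects(des, q_true = 2, noise_sd = 0.05, seed = 9)
  pm <- generate_dataset(des, eff, seed = 10)
  ppca_run <- suppressWarnings(
    run_imputation_validation(pm, "ppca", orders = 2, n_iterations = 5,
                              seed = 11))
  plsr_run <- run_imputation_validation(pm, "plsr", orders = 2,
                                        n_iterations = 5, seed = 11)
  expect_gt(ppca_run$r2$mean_metric, 90)
  expect_gt(plsr_run$r2$mean_metric, 90)
})
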