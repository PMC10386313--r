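# The two validation protocols:
#  (A) hybrid Monte-Carlo cross + external validation for classification:
#      per iteration ~85% of the complete samples per month go to
#      calibration together with the calibration-eligible partial samples;
#      the remaining complete samples form the internal cross-validation
#      pool and a fixed set of partial samples (chosen once per run, never
#      calibrated on) forms the external validation pool;
#  (B) Monte-Carlo cross-validation for %FAME imputation: per iteration 20%
#      of the complete samples per month have their %FAME block masked and
#      are predicted from their minerals.

#' Build one calibration/validation split
#'
#' Per month, approximately `calibration_fraction` of the complete samples
#' (nearest integer, at least one left out) are drawn into calibration; the
#' rest form the internal cross-validation pool. Partial samples are divided
#' into a fixed external-validation pool (`external_ids`, held out of every
#' calibration set) and a calibration-eligible pool that joins the
#' calibration set in full. With the default 45-sample design the per-month
#' (complete, partial) calibration counts are (10,2), (10,2), (8,4) and the
#' validation counts (2,1), (2,1), (1,2).
#'
#' @param pm A `profile_matrix` with complete and partial samples.
#' @param seed Iteration seed driving the random complete-sample split.
#' @param calibration_fraction Fraction of complete samples calibrated on
#'   (default 0.85).
#' @param external_ids Sample ids of the fixed external partial pool. When
#'   `NULL`, defaults per month to the last `max(1, round(n_partial / 3))`
#'   partial samples (deterministic); [run_classification_validation()]
#'   draws this pool randomly once per run instead.
#' @return A list of class `split_plan` with the four disjoint id sets
#'   `calibration_complete`, `calibration_partial`, `validation_complete`,
#'   `validation_partial_external`, plus a per-month `counts` table.
#' @export
make_classification_split <- function(pm, seed, calibration_fraction = 0.85,
                                      external_ids = NULL) {
  months <- levels(pm$labels)
  complete <- pm$completeness == "complete"
  if (is.null(external_ids)) {
    external_ids <- unlist(lapply(months, function(m) {
      ids <- pm$sample_ids[pm$labels == m & !complete]
      np <- length(ids)
      if (np == 0) return(character(0))
      utils::tail(ids, max(1L, round(np / 3)))
    }))
  }
  if (!all(external_ids %in% pm$sample_ids[!complete])) {
    stop("`external_ids` must name partial samples")
  }

  cal_c <- cal_p <- val_c <- character(0)
  counts <- NULL
  with_seed(seed, {
    for (m in months) {
      cm <- pm$sample_ids[pm$labels == m & complete]
      nm <- length(cm)
      if (nm < 2) stop("month ", m, " has fewer than 2 complete samples")
      n_cal <- min(max(1L, round(calibration_fraction * nm)), nm - 1L)
      pick <- sample.int(nm, n_cal)
      cal_c <- c(cal_c, cm[pick])
      val_c <- c(val_c, cm[-pick])
      pm_ids <- pm$sample_ids[pm$labels == m & !complete]
      cal_p <- c(cal_p, setdiff(pm_ids, external_ids))
      counts <- rbind(counts, data.frame(
        month = m, calibration_complete = n_cal,
        calibration_partial = length(setdiff(pm_ids, external_ids)),
        validation_complete = nm - n_cal,
        validation_partial = sum(pm_ids %in% external_ids),
        stringsAsFactors = FALSE))
    }
  })
  structure(list(calibration_complete = cal_c,
                 calibration_partial = cal_p,
                 validation_complete = val_c,
                 validation_partial_external = external_ids,
                 counts = counts),
            class = "split_plan")
}

#' Fraction of correct classifications, in percent
#'
#' @param predicted,truth Equal-length label vectors.
#' @return `100 * mean(predicted == truth)`.
#' @export
percent_correct <- function(predicted, truth) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  100 * mean(as.character(predicted) == as.character(truth))
}

#' Root mean square of a residual set
#'
#' @param residuals Numeric vector of residuals.
#' @return `sqrt(mean(residuals^2))`.
#' @export
rmse <- function(residuals) {
  if (length(residuals) == 0) stop("empty input")
  sqrt(mean(residuals^2))
}

#' Coefficient of determination from residuals and total deviations
#'
#' @param residuals Residual set (prediction errors).
#' @param totals Total deviations (truth minus the calibration mean).
#' @return `1 - sum(residuals^2) / sum(totals^2)`.
#' @export
r_squared <- function(residuals, totals) {
  if (length(residuals) == 0 || length(totals) == 0) stop("empty input")
  sst <- sum(totals^2)
  if (sst <= 0) stop("zero total sum of squares")
  1 - sum(residuals^2) / sst
}

# ---- protocol A: classification ------------------------------------------

#' Monte-Carlo cross + external validation of classification
#'
#' Sweeps the model order: per iteration the data are split with
#' [make_classification_split()] (same splits across orders, so the order
#' comparison uses common random draws), preprocessing is fitted on
#' calibration only, the model is fitted on calibration (`"ppca_lda"` uses
#' complete *and* partial calibration samples on all 81 variables;
#' `"plsda"` uses the mineral block only), and all validation samples
#' (internal complete + external partial) are classified against their known
#' month labels. The %CC curve averages over iterations; the selected order
#' maximises the mean %CC (ties toward the smaller order).
#'
#' @param pm A `profile_matrix`.
#' @param model `"ppca_lda"` or `"plsda"`.
#' @param orders Model orders (PCs or LVs) to sweep.
#' @param n_iterations Monte-Carlo iterations (default 20).
#' @param seed Master seed; the external pool draw and all iteration splits
#'   derive from it.
#' @param calibration_fraction See [make_classification_split()].
#' @param lda_components `"all"` (classify on all retained PCs, default) or
#'   `"two"` (classify on the first two PCs of the q-component model, the
#'   visualisation view).
#' @param ppca_tol,ppca_max_iter EM settings for the inner PPCA fits.
#' @return A list of class `classification_validation`: `curve` (the overall
#'   %CC [metric_curve()]), `internal_curve` and `external_curve`
#'   (per-pool breakdowns), `splits` (one `split_plan` per iteration), and
#'   the run settings.
#' @export
run_classification_validation <- function(pm, model = c("ppca_lda", "plsda"),
                                          orders = 1:8, n_iterations = 20L,
                                          seed = 1L,
                                          calibration_fraction = 0.85,
                                          lda_components = c("all", "two"),
                                          ppca_tol = 1e-7,
                                          ppca_max_iter = 2000L) {
  model <- match.arg(model)
  lda_components <- match.arg(lda_components)
  orders <- as.integer(orders)
  if (any(orders < 1)) stop("orders must be >= 1")
  minerals <- mineral_cols(pm)
  if (model == "plsda" && any(orders > length(minerals))) {
    stop("PLS-DA orders cannot exceed the ", length(minerals),
         " mineral predictors")
  }

  run <- with_seed(seed, {
    months <- levels(pm$labels)
    external_ids <- unlist(lapply(months, function(m) {
      ids <- pm$sample_ids[pm$labels == m & pm$completeness == "partial"]
      np <- length(ids)
      if (np == 0) return(character(0))
      ids[sample.int(np, max(1L, round(np / 3)))]
    }))
    list(external_ids = external_ids, iter_seeds = draw_seeds(n_iterations))
  })

  acc <- acc_int <- acc_ext <- matrix(
    NA_real_, length(orders), n_iterations)
  splits <- vector("list", n_iterations)

  for (i in seq_len(n_iterations)) {
    plan <- make_classification_split(pm, seed = run$iter_seeds[i],
                                      calibration_fraction = calibration_fraction,
                                      external_ids = run$external_ids)
    splits[[i]] <- plan
    cal_ids <- c(plan$calibration_complete, plan$calibration_partial)
    val_ids <- c(plan$validation_complete, plan$validation_partial_external)
    int_idx <- seq_along(plan$validation_complete)
    truth <- pm$labels[match(val_ids, pm$sample_ids)]

    if (model == "ppca_lda") {
      scaler <- fit_scaler(pm, cal_ids)
      scaled <- apply_scaler(scaler, pm)
      cal <- scaled[cal_ids]
      val <- scaled[val_ids]
      cal_labels <- cal$labels
      for (k in seq_along(orders)) {
        fit <- fit_ppca(cal, orders[k], tol = ppca_tol,
                        max_iter = ppca_max_iter)
        cal_sc <- ppca_scores(fit, cal)$scores
        val_sc <- ppca_scores(fit, val)$scores
        if (lda_components == "two" && orders[k] >= 2) {
          cal_sc <- cal_sc[, 1:2, drop = FALSE]
          val_sc <- val_sc[, 1:2, drop = FALSE]
        }
        lda_fit <- fit_lda(cal_sc, cal_labels)
        pred <- classify_lda(lda_fit, val_sc)
        acc[k, i] <- percent_correct(pred, truth)
        acc_int[k, i] <- percent_correct(pred[int_idx], truth[int_idx])
        acc_ext[k, i] <- percent_correct(pred[-int_idx], truth[-int_idx])
      }
    } else {
      cal_idx <- match(cal_ids, pm$sample_ids)
      val_idx <- match(val_ids, pm$sample_ids)
      Xcal <- pm$values[cal_idx, minerals, drop = FALSE]
      Xval <- pm$values[val_idx, minerals, drop = FALSE]
      for (k in seq_along(orders)) {
        fit <- fit_plsda(Xcal, pm$labels[cal_idx], orders[k])
        pred <- predict(fit, Xval)
        acc[k, i] <- percent_correct(pred, truth)
        acc_int[k, i] <- percent_correct(pred[int_idx], truth[int_idx])
        acc_ext[k, i] <- percent_correct(pred[-int_idx], truth[-int_idx])
      }
    }
  }

  structure(list(
    curve = metric_curve(orders, acc, "%CC"),
    internal_curve = metric_curve(orders, acc_int, "%CC (internal)"),
    external_curve = metric_curve(orders, acc_ext, "%CC (external)"),
    splits = splits, model = model, seed = seed,
    external_ids = run$external_ids, lda_components = lda_components),
    class = "classification_validation")
}

# ---- protocol B: imputation ----------------------------------------------

#' Monte-Carlo cross-validation of %FAME imputation
#'
#' Per iteration, 20% of the complete samples per month (nearest integer, at
#' least one) are held out and their %FAME block masked; the model is fitted
#' on the remaining samples (PPCA additionally uses the partial samples) and
#' predicts the held-out %FAME values from the minerals (PPCA: conditional
#' mean given the observed coordinates; PLSR: regression of the %FAME block
#' on the mineral block). Residuals are pooled within an iteration; curves
#' report the per-iteration RMSECV and R-squared (in percent, relative to
#' the calibration %FAME means) averaged over iterations, on the autoscaled
#' scale, with original-scale analogues alongside.
#'
#' @param pm A `profile_matrix` whose complete samples carry %FAME ground
#'   truth.
#' @param model `"ppca"` or `"plsr"`.
#' @param orders Model orders (PCs or LVs) to sweep.
#' @param n_iterations Monte-Carlo iterations (default 20).
#' @param seed Master seed.
#' @param holdout_fraction Per-month fraction of complete samples held out
#'   (default 0.2).
#' @param ppca_tol,ppca_max_iter EM settings for the inner PPCA fits.
#' @return A list of class `imputation_validation` with `rmsecv` and `r2`
#'   [metric_curve()]s on the autoscaled scale (R2 in percent; selected
#'   orders minimise RMSECV / maximise R2), `rmsecv_original` and
#'   `r2_original` on the measurement scale, and run settings.
#' @export
run_imputation_validation <- function(pm, model = c("ppca", "plsr"),
                                      orders = 1:8, n_iterations = 20L,
                                      seed = 1L, holdout_fraction = 0.2,
                                      ppca_tol = 1e-7,
                                      ppca_max_iter = 2000L) {
  model <- match.arg(model)
  orders <- as.integer(orders)
  minerals <- mineral_cols(pm)
  fame <- fame_cols(pm)
  if (model == "plsr" && any(orders > length(minerals))) {
    stop("PLSR orders cannot exceed the ", length(minerals),
         " mineral predictors")
  }
  months <- levels(pm$labels)
  complete_ids <- split(pm$sample_ids[pm$completeness == "complete"],
                        droplevels(pm$labels[pm$completeness == "complete"]))
  if (any(lengths(complete_ids[months]) < 2)) {
    stop("every month needs at least 2 complete samples")
  }

  iter_seeds <- with_seed(seed, draw_seeds(n_iterations))
  m_rmse <- m_r2 <- m_rmse_o <- m_r2_o <-
    matrix(NA_real_, length(orders), n_iterations)

  for (i in seq_len(n_iterations)) {
    held <- with_seed(iter_seeds[i], unlist(lapply(months, function(m) {
      ids <- complete_ids[[m]]
      k <- min(max(1L, round(holdout_fraction * length(ids))),
               length(ids) - 1L)
      ids[sample.int(length(ids), k)]
    })))
    cal_ids <- setdiff(pm$sample_ids, held)

    scaler <- fit_scaler(pm, cal_ids)
    scaled <- apply_scaler(scaler, pm)
    truth_scaled <- scaled$values[match(held, pm$sample_ids), fame,
                                  drop = FALSE]
    truth_raw <- pm$values[match(held, pm$sample_ids), fame, drop = FALSE]
    # totals relative to the calibration FAME means (zero on the scaled
    # scale by construction of the scaler)
    tot_scaled <- truth_scaled
    tot_raw <- sweep(truth_raw, 2, scaler$center[fame])

    if (model == "ppca") {
      cal <- scaled[cal_ids]
      test <- scaled[held]
      test_masked_vals <- test$values
      test_masked_vals[, fame] <- NA_real_
      test_masked <- profile_matrix(
        test_masked_vals, sample_ids = test$sample_ids, labels = test$labels,
        var_names = test$var_names, var_roles = test$var_roles)
      for (k in seq_along(orders)) {
        fit <- fit_ppca(cal, orders[k], tol = ppca_tol,
                        max_iter = ppca_max_iter)
        rec <- ppca_reconstruct(fit, test_masked)
        pred_scaled <- rec$values[, fame, drop = FALSE]
        res_scaled <- pred_scaled - truth_scaled
        res_raw <- sweep(res_scaled, 2, scaler$scale[fame], `*`)
        m_rmse[k, i] <- rmse(as.vector(res_scaled))
        m_r2[k, i] <- 100 * r_squared(as.vector(res_scaled),
                                      as.vector(tot_scaled))
        m_rmse_o[k, i] <- rmse(as.vector(res_raw))
        m_r2_o[k, i] <- 100 * r_squared(as.vector(res_raw),
                                        as.vector(tot_raw))
      }
    } else {
      cal_complete <- intersect(cal_ids,
                                pm$sample_ids[pm$completeness == "complete"])
      cal_idx <- match(cal_complete, pm$sample_ids)
      Xcal <- pm$values[cal_idx, minerals, drop = FALSE]
      Ycal <- pm$values[cal_idx, fame, drop = FALSE]
      Xtest <- pm$values[match(held, pm$sample_ids), minerals, drop = FALSE]
      for (k in seq_along(orders)) {
        fit <- fit_pls(Xcal, Ycal, orders[k])
        pred_raw <- predict(fit, Xtest)
        res_raw <- pred_raw - truth_raw
        res_scaled <- sweep(res_raw, 2, scaler$scale[fame], `/`)
        m_rmse[k, i] <- rmse(as.vector(res_scaled))
        m_r2[k, i] <- 100 * r_squared(as.vector(res_scaled),
                                      as.vector(tot_scaled))
        m_rmse_o[k, i] <- rmse(as.vector(res_raw))
        m_r2_o[k, i] <- 100 * r_squared(as.vector(res_raw),
                                        as.vector(tot_raw))
      }
    }
  }

  structure(list(
    rmsecv = metric_curve(orders, m_rmse, "RMSECV", higher_is_better = FALSE),
    r2 = metric_curve(orders, m_r2, "R2"),
    rmsecv_original = metric_curve(orders, m_rmse_o, "RMSECV (original scale)",
                                   higher_is_better = FALSE),
    r2_original = metric_curve(orders, m_r2_o, "R2 (original scale)"),
    model = model, seed = seed),
    class = "imputation_validation")
}
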