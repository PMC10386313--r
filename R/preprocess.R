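# Unit-variance (autoscaling) preprocessing. Centering and scaling are
# always fitted on the calibration subset only, over observed cells only,
# so validation values never leak into the statistics.

#' Fit an autoscaler on (a subset of) a profile matrix
#'
#' Per-variable center (mean) and scale (standard deviation, n-1 denominator)
#' computed over the *observed* cells of the selected samples.
#'
#' @param pm A `profile_matrix`.
#' @param sample_subset Optional sample ids or indices; defaults to all
#'   samples.
#' @return An object of class `profile_scaler` with `center`, `scale` and
#'   `fitted_on` fields.
#' @export
fit_scaler <- function(pm, sample_subset = NULL) {
  sub <- if (is.null(sample_subset)) pm else pm[sample_subset]
  vals <- sub$values
  n_obs <- colSums(sub$mask)
  too_few <- n_obs < 2
  if (any(too_few)) {
    stop("variables with fewer than 2 observed values in the fitting subset: ",
         paste(pm$var_names[too_few], collapse = ", "))
  }
  center <- colMeans(vals, na.rm = TRUE)
  scale <- apply(vals, 2, stats::sd, na.rm = TRUE)
  zero <- scale <= 0 | !is.finite(scale)
  if (any(zero)) {
    stop("zero-variance variables in the fitting subset: ",
         paste(pm$var_names[zero], collapse = ", "))
  }
  structure(list(center = center, scale = scale,
                 var_names = pm$var_names, fitted_on = sub$sample_ids),
            class = "profile_scaler")
}

#' Apply (or invert) an autoscaler
#'
#' Transforms observed cells to `(x - center) / scale` (or back, with
#' `inverse = TRUE`). The mask is preserved; `apply_scaler(sc, apply_scaler(
#' sc, pm), inverse = TRUE)` returns the input to machine precision.
#'
#' @param scaler A `profile_scaler`.
#' @param pm A `profile_matrix` with the same variables.
#' @param inverse Undo the scaling instead of applying it.
#' @return A transformed `profile_matrix`.
#' @export
apply_scaler <- function(scaler, pm, inverse = FALSE) {
  if (!identical(scaler$var_names, pm$var_names)) {
    stop("scaler and profile matrix have different variables")
  }
  vals <- pm$values
  if (inverse) {
    vals <- sweep(sweep(vals, 2, scaler$scale, `*`), 2, scaler$center, `+`)
  } else {
    vals <- sweep(sweep(vals, 2, scaler$center, `-`), 2, scaler$scale, `/`)
  }
  vals[!pm$mask] <- NA_real_
  profile_matrix(vals, mask = pm$mask, sample_ids = pm$sample_ids,
                 labels = pm$labels, var_names = pm$var_names,
                 var_roles = pm$var_roles, completeness = pm$completeness)
}
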