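# Synthetic profile generator.
#
# The downstream analysis assumes low-rank Gaussian profiles with
# season-dependent mean shifts and a block-missing design (partial samples
# lack the whole %FAME block). The generator draws exactly that structure:
#   x = mu + W_true (z0 + offset_class) + eps,  z0 ~ N(0, I_q),
#   eps ~ N(0, noise_sd^2 I_p),
# so the marginal covariance is W W' + noise_sd^2 I and class separation
# lives in latent space. No attempt is made at chemical realism
# (compositional closure, chain-length kinetics): only the statistical
# structure the analysis assumes.

#' Study design: sample counts and variable split
#'
#' Defaults reproduce the motivating 45-sample design: three production
#' months (January, April, June), 12/12/9 complete samples, 3/3/6 partial
#' samples (mineral-only), 73 %FAME variables plus 8 minerals.
#'
#' @param months Class labels in order.
#' @param complete_counts,partial_counts Per-month sample counts.
#' @param n_fame,n_minerals Number of %FAME and mineral variables.
#' @return A list of class `study_design`.
#' @export
study_design <- function(months = c("January", "April", "June"),
                         complete_counts = c(12L, 12L, 9L),
                         partial_counts = c(3L, 3L, 6L),
                         n_fame = 73L, n_minerals = 8L) {
  k <- length(months)
  stopifnot(length(complete_counts) == k, length(partial_counts) == k,
            all(complete_counts >= 0), all(partial_counts >= 0),
            n_fame >= 0, n_minerals >= 0, n_fame + n_minerals >= 1)
  if (n_minerals > length(MINERAL_NAMES)) {
    stop("at most ", length(MINERAL_NAMES), " mineral variables are supported")
  }
  structure(list(months = months,
                 complete_counts = as.integer(complete_counts),
                 partial_counts = as.integer(partial_counts),
                 n_fame = as.integer(n_fame),
                 n_minerals = as.integer(n_minerals)),
            class = "study_design")
}

# default orientation of mineral loadings on the first two latent axes.
# Month effects enter as latent offsets with January ~ (+, -), April ~ (+, +),
# June ~ (-, 0), so these signs encode: S, P, Ca tracking April; K, Zn
# tracking January; Na tracking June; Fe weakly winter; Mg near-inert.
default_mineral_signs <- function() {
  m <- rbind(Ca = c(1, 1), Mg = c(1, -1), Na = c(-1, 1), K = c(1, -1),
             P = c(1, 1), S = c(1, 1), Zn = c(1, -1), Fe = c(1, -1))
  colnames(m) <- c("axis1", "axis2")
  m
}

# relative loading magnitude of each mineral on axes 1-2 (Mg weak, Fe weakish)
default_mineral_weights <- function() {
  c(Ca = 1, Mg = 0.05, Na = 1, K = 1, P = 1, S = 1, Zn = 1, Fe = 0.3)
}

#' Season effects: latent structure of the generator
#'
#' Draws a full-column-rank true loading matrix with geometrically decaying
#' per-axis scales and heterogeneous per-variable scale factors, orients the
#' mineral rows on the first two axes according to a fixed sign pattern, and
#' sets per-month latent mean offsets. With the default month order the
#' offsets put January and April at positive axis 1 and June negative, April
#' positive / January negative on axis 2, reproducing the score geometry the
#' classifier is meant to separate.
#'
#' @param design A [study_design()].
#' @param q_true Generating latent rank (default 5).
#' @param noise_sd Isotropic residual standard deviation (default 1).
#' @param axis_scales Per-axis loading scales, length `q_true`; default
#'   `2.2 * 0.7^(0:(q_true-1))`.
#' @param offset_scale Magnitude of the per-month latent mean offsets on the
#'   first two axes (default 1.5, in prior-SD units of the latent scores).
#' @param scale_log_sd SD of the log-normal per-variable scale factors
#'   (default 0.4); set to 0 for homogeneous variable scales.
#' @param mineral_signs 2-column sign matrix (axis1, axis2) with one row per
#'   mineral; default pattern described above.
#' @param mineral_strength Magnitude of the mineral loadings on the first
#'   two axes relative to the axis scale (default 0.35). Kept well below 1
#'   so the 73-variable FAME block carries most of the class signal and a
#'   mineral-only model is informative but distinctly weaker.
#' @param seed Seed for the random draws inside the effects.
#' @return A list of class `season_effects` with elements `loadings_true`
#'   (p x q_true), `class_offsets` (month x q_true), `noise_sd`, `mu`,
#'   `var_scales` and bookkeeping.
#' @export
season_effects <- function(design = study_design(), q_true = 5L,
                           noise_sd = 1, axis_scales = NULL,
                           offset_scale = 1.5, scale_log_sd = 0.4,
                           mineral_signs = NULL, mineral_strength = 0.35,
                           seed = 2301L) {
  p <- design$n_fame + design$n_minerals
  q_true <- as.integer(q_true)
  if (q_true < 1 || q_true > p) stop("`q_true` must be in [1, p]")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  axis_scales <- axis_scales %||% (2.2 * 0.7^(seq_len(q_true) - 1))
  stopifnot(length(axis_scales) == q_true, all(axis_scales > 0))
  mineral_signs <- mineral_signs %||%
    default_mineral_signs()[seq_len(design$n_minerals), , drop = FALSE]

  var_names <- c(sprintf("FAME_%02d", seq_len(design$n_fame)),
                 MINERAL_NAMES[seq_len(design$n_minerals)])

  with_seed(seed, {
    var_scales <- exp(stats::rnorm(p, 0, scale_log_sd))
    W <- matrix(stats::rnorm(p * q_true), p, q_true)
    W <- sweep(W, 2, axis_scales, `*`)
    # orient mineral rows on the first two axes to the configured sign
    # pattern with deterministic magnitudes (Mg/Fe damped), so the implied
    # month-mineral correlations do not depend on the random draw
    if (design$n_minerals > 0) {
      min_rows <- design$n_fame + seq_len(design$n_minerals)
      wts <- default_mineral_weights()[seq_len(design$n_minerals)]
      for (a in seq_len(min(2L, q_true))) {
        W[min_rows, a] <- mineral_signs[, a] * wts * mineral_strength *
          axis_scales[a]
      }
    }
    W <- W * var_scales
    mu <- exp(stats::rnorm(p, 1, 0.5)) * var_scales
  })

  k <- length(design$months)
  offsets <- matrix(0, k, q_true, dimnames = list(design$months, NULL))
  # class separation on the first two latent axes (see Details)
  ax1 <- c(1, 1, -1)[seq_len(min(k, 3))]
  ax2 <- c(-1, 1, 0)[seq_len(min(k, 3))]
  offsets[seq_along(ax1), 1] <- offset_scale * ax1
  if (q_true >= 2) offsets[seq_along(ax2), 2] <- offset_scale * ax2

  structure(list(q_true = q_true, loadings_true = W, mu = mu,
                 class_offsets = offsets, noise_sd = noise_sd,
                 var_scales = var_scales, var_names = var_names,
                 mineral_signs = mineral_signs, seed = as.integer(seed)),
            class = "season_effects")
}

#' Generate a synthetic profile dataset
#'
#' Draws `x = mu + W (z0 + offset_month) + eps` per sample with standard
#' normal latent scores and isotropic Gaussian noise, then applies the
#' block-missing design: each month's partial samples have the entire %FAME
#' block masked. Identical `design`/`effects`/`seed` give bitwise-identical
#' output.
#'
#' @param design A [study_design()].
#' @param effects A [season_effects()] built for the same design.
#' @param seed Integer seed controlling the sample draws.
#' @return A [profile_matrix()] with labels and complete/partial tags set.
#' @export
generate_dataset <- function(design = study_design(),
                             effects = season_effects(design), seed = 1L) {
  p <- design$n_fame + design$n_minerals
  if (nrow(effects$loadings_true) != p) {
    stop("`effects` loadings do not match the design's variable count")
  }
  q <- effects$q_true
  counts <- design$complete_counts + design$partial_counts
  n <- sum(counts)
  if (n < 1) stop("design has no samples")

  months <- rep(design$months, counts)
  completeness <- unlist(lapply(seq_along(design$months), function(m) {
    c(rep("complete", design$complete_counts[m]),
      rep("partial", design$partial_counts[m]))
  }))
  ids <- unlist(lapply(seq_along(design$months), function(m) {
    sprintf("%s_%02d", substr(design$months[m], 1, 3), seq_len(counts[m]))
  }))

  vals <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * q), n, q)
    z <- z + effects$class_offsets[months, , drop = FALSE]
    eps <- matrix(stats::rnorm(n * p, 0, effects$noise_sd), n, p)
    sweep(z %*% t(effects$loadings_true) + eps, 2, effects$mu, `+`)
  })
  colnames(vals) <- effects$var_names

  mask <- matrix(TRUE, n, p)
  mask[completeness == "partial", seq_len(design$n_fame)] <- FALSE
  vals[!mask] <- NA_real_

  profile_matrix(vals, mask = mask, sample_ids = ids, labels = months,
                 var_names = effects$var_names,
                 var_roles = c(rep("FAME", design$n_fame),
                               rep("mineral", design$n_minerals)))
}

#' Apply a missingness pattern to a profile matrix
#'
#' `pattern = "block"` masks the whole %FAME block of selected samples (the
#' study's partial-sample pattern), choosing `counts[m]` currently-complete
#' samples per month. `pattern = "random"` masks observed cells independently
#' with probability `fraction`.
#'
#' @param pm A `profile_matrix`.
#' @param pattern `"block"` or `"random"`.
#' @param counts Per-month numbers of samples to convert to partial
#'   (block pattern).
#' @param fraction Cell-wise missing probability (random pattern).
#' @param seed Integer seed.
#' @return A `profile_matrix` with updated mask and completeness tags.
#' @export
apply_missing_pattern <- function(pm, pattern = c("block", "random"),
                                  counts = NULL, fraction = NULL, seed = 1L) {
  pattern <- match.arg(pattern)
  mask <- pm$mask
  if (pattern == "block") {
    months <- levels(pm$labels)
    counts <- counts %||% rep(0L, length(months))
    if (length(counts) != length(months)) {
      stop("`counts` must have one entry per month")
    }
    fame <- fame_cols(pm)
    with_seed(seed, {
      for (m in seq_along(months)) {
        pool <- which(pm$labels == months[m] & pm$completeness == "complete")
        if (counts[m] > length(pool)) {
          stop(sprintf("month %s has %d complete samples, %d requested",
                       months[m], length(pool), counts[m]))
        }
        if (counts[m] > 0) {
          chosen <- pool[sample.int(length(pool), counts[m])]
          mask[chosen, fame] <- FALSE
        }
      }
    })
  } else {
    if (is.null(fraction) || fraction < 0 || fraction > 1) {
      stop("`fraction` must be in [0, 1] for the random pattern")
    }
    with_seed(seed, {
      drop <- matrix(stats::runif(length(mask)) < fraction,
                     nrow(mask), ncol(mask))
      mask <- mask & !drop
    })
  }
  vals <- pm$values
  vals[!mask] <- NA_real_
  profile_matrix(vals, mask = mask, sample_ids = pm$sample_ids,
                 labels = pm$labels, var_names = pm$var_names,
                 var_roles = pm$var_roles)
}
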