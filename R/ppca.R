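# Probabilistic PCA under the isotropic latent-variable model
#
#   x = W z + mu + eps,  z ~ N(0, I_q),  eps ~ N(0, sigma2 I_p),
#
# fitted by EM on the observed-data likelihood over arbitrary missingness
# masks. Both the latent scores z and the missing coordinates x_miss are
# treated as latent in the E-step; the M-step updates (mu, W) jointly by a
# weighted regression and sigma2 in closed form, which makes the observed
# log-likelihood provably non-decreasing. Samples sharing a missingness
# pattern are processed as one matrix block, so the two-pattern
# complete/mineral-only design costs two matrix operations per iteration.

# ---- internal: coerce input to values+mask -------------------------------

as_values_mask <- function(x) {
  if (inherits(x, "profile_matrix")) {
    list(values = x$values, mask = x$mask, var_names = x$var_names,
         var_roles = x$var_roles, sample_ids = x$sample_ids)
  } else {
    x <- as.matrix(x)
    list(values = x, mask = !is.na(x),
         var_names = colnames(x) %||% paste0("V", seq_len(ncol(x))),
         var_roles = NULL, sample_ids = rownames(x))
  }
}

# group rows by identical missingness pattern; returns list of
# list(rows, obs) with obs the observed column indices
pattern_groups <- function(mask) {
  keys <- apply(mask, 1L, function(r) rawToChar(as.raw(r + 48L)))
  idx <- split(seq_len(nrow(mask)), keys)
  lapply(idx, function(rows) list(rows = rows, obs = which(mask[rows[1], ])))
}

# observed-data log-likelihood at (W, mu, sigma2), via Woodbury per pattern
ppca_loglik <- function(X, groups, W, mu, sigma2) {
  q <- ncol(W)
  ll <- 0
  for (g in groups) {
    o <- g$obs
    lo <- length(o)
    if (lo == 0L) next
    D <- sweep(X[g$rows, o, drop = FALSE], 2, mu[o])
    Wo <- W[o, , drop = FALSE]
    M <- crossprod(Wo) + diag(sigma2, q)
    Minv <- chol2inv(chol(M))
    G <- D %*% Wo
    qf <- (rowSums(D^2) - rowSums((G %*% Minv) * G)) / sigma2
    ldet <- (lo - q) * log(sigma2) +
      as.numeric(determinant(M, logarithm = TRUE)$modulus)
    ll <- ll - 0.5 * sum(lo * log(2 * pi) + ldet + qf)
  }
  ll
}

#' Fit probabilistic PCA by EM over a missingness mask
#'
#' Maximum-likelihood estimation of the loading matrix `W` (p x q), mean
#' `mu` and isotropic noise variance `sigma2` from data with arbitrarily
#' missing cells. On complete data the solution coincides with the classical
#' PCA eigendecomposition closed form. After convergence `W` is rotated to
#' ordered principal axes (`W'W` diagonal, descending) with the sign of each
#' component fixed so that its largest-magnitude loading is positive.
#'
#' @param x A `profile_matrix` (typically autoscaled) or a numeric matrix
#'   with `NA` marking missing cells.
#' @param q Number of components, `1 <= q < p`.
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param init `"eigen"` (deterministic: eigendecomposition of the
#'   mean-imputed covariance) or `"random"`.
#' @param seed Seed used only for `init = "random"`.
#' @return An object of class `ppca_model`: `W`, `mu`, `sigma2`, `q`,
#'   `ll_trace` (observed-data log-likelihood per iteration, non-decreasing),
#'   `converged`, `explained_variance` (per-component fraction of the total
#'   observed variance of the fitting data), and bookkeeping.
#' @export
fit_ppca <- function(x, q, tol = 1e-8, max_iter = 2000L,
                     init = c("eigen", "random"), seed = NULL) {
  init <- match.arg(init)
  vm <- as_values_mask(x)
  X <- vm$values
  mask <- vm$mask
  p <- ncol(X)
  q <- as.integer(q)
  if (q < 1 || q >= p) stop("`q` must satisfy 1 <= q < p")

  # fully missing rows carry no likelihood information; drop from fitting
  keep <- rowSums(mask) > 0L
  X <- X[keep, , drop = FALSE]
  mask <- mask[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples with observed cells")
  if (any(colSums(mask) < 2)) {
    stop("every variable must be observed in at least 2 samples: ",
         paste(vm$var_names[colSums(mask) < 2], collapse = ", "))
  }
  X[!mask] <- NA_real_

  # total observed variance (for explained-variance fractions)
  total_var <- sum(apply(X, 2, stats::var, na.rm = TRUE))

  # initialisation: eigendecomposition of the mean-imputed covariance
  col_mu <- colMeans(X, na.rm = TRUE)
  Ximp <- X
  for (j in seq_len(p)) Ximp[is.na(Ximp[, j]), j] <- col_mu[j]
  if (init == "eigen") {
    S <- crossprod(sweep(Ximp, 2, col_mu)) / n
    es <- eigen(S, symmetric = TRUE)
    lam <- pmax(es$values, 0)
    sigma2 <- max(mean(lam[(q + 1):p]), 1e-8)
    W <- es$vectors[, seq_len(q), drop = FALSE] %*%
      diag(sqrt(pmax(lam[seq_len(q)] - sigma2, 1e-8)), q)
    mu <- col_mu
  } else {
    if (is.null(seed)) stop("`seed` is required for random initialisation")
    W <- with_seed(seed, matrix(stats::rnorm(p * q), p, q))
    sigma2 <- 1
    mu <- col_mu
  }

  groups <- pattern_groups(mask)
  X0 <- X
  X0[!mask] <- 0  # placeholder; masked cells are never read via groups

  ll_trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L

  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    # ---- E-step (and observed-data log-likelihood at current params) ----
    A <- matrix(0, q + 1, q + 1)  # sum of <z~ z~'> with z~ = (1, z)
    C <- matrix(0, p, q + 1)      # sum of <x z~'>
    Sxx <- 0                      # sum of <x_ij^2>
    ll <- 0
    for (g in groups) {
      o <- g$obs
      u <- setdiff(seq_len(p), o)
      rows <- g$rows
      ng <- length(rows)
      lo <- length(o)
      Xo <- X0[rows, o, drop = FALSE]
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + diag(sigma2, q)
      Minv <- chol2inv(chol(M))
      D <- sweep(Xo, 2, mu[o])
      G <- D %*% Wo                    # ng x q
      Zm <- G %*% Minv                 # posterior means of z
      Sz <- sigma2 * Minv              # posterior covariance (shared)
      sumZ <- colSums(Zm)
      SS <- ng * Sz + crossprod(Zm)    # sum of <z z'>

      A[1, 1] <- A[1, 1] + ng
      A[1, -1] <- A[1, -1] + sumZ
      A[-1, 1] <- A[-1, 1] + sumZ
      A[-1, -1] <- A[-1, -1] + SS

      C[o, 1] <- C[o, 1] + colSums(Xo)
      C[o, -1] <- C[o, -1] + crossprod(Xo, Zm)
      Sxx <- Sxx + sum(Xo^2)

      if (length(u)) {
        Wu <- W[u, , drop = FALSE]
        Xu_mean <- sweep(Zm %*% t(Wu), 2, mu[u], `+`)   # <x_u>
        C[u, 1] <- C[u, 1] + colSums(Xu_mean)
        C[u, -1] <- C[u, -1] + outer(mu[u], sumZ) + Wu %*% SS
        var_u <- sigma2 + rowSums((Wu %*% Sz) * Wu)
        Sxx <- Sxx + sum(Xu_mean^2) + ng * sum(var_u)
      }

      # observed-data log-likelihood of this block
      qf <- (rowSums(D^2) - rowSums((G %*% Minv) * G)) / sigma2
      ldet <- (lo - q) * log(sigma2) +
        as.numeric(determinant(M, logarithm = TRUE)$modulus)
      ll <- ll - 0.5 * sum(lo * log(2 * pi) + ldet + qf)
    }
    if (iter >= 2) {
      prev <- ll_trace[iter - 1]
      if (ll < prev) {
        # the exact M-step makes the likelihood non-decreasing in exact
        # arithmetic, so a decrease marks the numerical floor (near-singular
        # M at sigma2 -> 0): restore the better parameters and stop
        W <- W_prev
        mu <- mu_prev
        sigma2 <- sigma2_prev
        converged <- TRUE
        break
      }
      ll_trace <- c(ll_trace, ll)
      if (ll - prev < tol * abs(prev)) {
        converged <- TRUE
        break
      }
    } else {
      ll_trace <- c(ll_trace, ll)
    }

    # ---- M-step: B = [mu | W] from the joint normal equations ----
    W_prev <- W
    mu_prev <- mu
    sigma2_prev <- sigma2
    B <- t(solve(A, t(C)))
    mu <- B[, 1]
    W <- B[, -1, drop = FALSE]
    sigma2 <- max((Sxx - sum(B * C)) / (n * p), 1e-12)
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations")
  }

  # rotate to ordered principal axes: W = U d V' -> U d (W'W diagonal,
  # descending); flip signs so each component's largest |loading| is positive
  sv <- svd(W)
  W <- sv$u %*% diag(sv$d, q)
  for (k in seq_len(q)) {
    if (W[which.max(abs(W[, k])), k] < 0) W[, k] <- -W[, k]
  }
  rownames(W) <- vm$var_names

  ev <- sv$d^2 / total_var

  structure(list(W = W, mu = stats::setNames(mu, vm$var_names),
                 sigma2 = sigma2, q = q, ll_trace = ll_trace,
                 converged = converged, n_iter = n_iter,
                 singular_values = sv$d, explained_variance = ev,
                 total_var = total_var, var_names = vm$var_names,
                 var_roles = vm$var_roles, init = init),
            class = "ppca_model")
}

#' @export
print.ppca_model <- function(x, ...) {
  cat(sprintf("ppca_model: q = %d, p = %d, sigma2 = %.4g, %s after %d iterations\n",
              x$q, nrow(x$W), x$sigma2,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("  explained variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.ppca_model <- function(object, ...) {
  structure(object$ll_trace[length(object$ll_trace)],
            df = length(object$mu) * (object$q + 1) + 1, class = "logLik")
}

#' Posterior-mean latent scores
#'
#' For each sample the posterior mean of `z` given that sample's observed
#' coordinates, `E[z | x_obs] = (sigma2 I + Wo'Wo)^{-1} Wo'(x_obs - mu_obs)`.
#' A fully missing sample scores at the prior mean (the zero vector).
#'
#' @param model A fitted `ppca_model`.
#' @param x Data on the same (preprocessed) scale and variables as the fit.
#' @return A list with `scores` (n x q matrix) and `explained_variance`
#'   (per-component fraction, from the fitted model).
#' @export
ppca_scores <- function(model, x) {
  vm <- as_values_mask(x)
  if (ncol(vm$values) != nrow(model$W)) {
    stop("data and model have different numbers of variables")
  }
  if (!is.null(vm$var_names) && !identical(vm$var_names, model$var_names)) {
    stop("data and model variable names differ")
  }
  X <- vm$values
  X[!vm$mask] <- 0
  n <- nrow(X)
  q <- model$q
  Z <- matrix(0, n, q, dimnames = list(vm$sample_ids, paste0("PC", seq_len(q))))
  for (g in pattern_groups(vm$mask)) {
    o <- g$obs
    if (length(o) == 0L) next  # fully missing: prior mean 0
    Wo <- model$W[o, , drop = FALSE]
    M <- crossprod(Wo) + diag(model$sigma2, q)
    D <- sweep(X[g$rows, o, drop = FALSE], 2, model$mu[o])
    Z[g$rows, ] <- D %*% Wo %*% chol2inv(chol(M))
  }
  list(scores = Z, explained_variance = model$explained_variance)
}

#' Conditional-mean reconstruction of missing cells
#'
#' Replaces every missing cell by `E[x_miss | x_obs]` under the fitted model
#' (`mu_miss + W_miss E[z | x_obs]`); observed cells are returned unchanged
#' and the output mask is all-`TRUE`. Supply the calibration `scaler` to also
#' obtain the reconstruction on the original measurement scale.
#'
#' @param model A fitted `ppca_model`.
#' @param x A `profile_matrix` on the model's (preprocessed) scale.
#' @param scaler Optional `profile_scaler` used to back-transform.
#' @return A fully observed `profile_matrix`, or, when `scaler` is given, a
#'   list with elements `scaled` and `original`.
#' @export
ppca_reconstruct <- function(model, x, scaler = NULL) {
  vm <- as_values_mask(x)
  if (ncol(vm$values) != nrow(model$W)) {
    stop("data and model have different numbers of variables")
  }
  Z <- ppca_scores(model, x)$scores
  filled <- vm$values
  miss <- !vm$mask
  if (any(miss)) {
    Xhat <- sweep(Z %*% t(model$W), 2, model$mu, `+`)
    filled[miss] <- Xhat[miss]
  }
  out <- profile_matrix(filled, mask = matrix(TRUE, nrow(filled), ncol(filled)),
                        sample_ids = vm$sample_ids %||% NULL,
                        labels = if (inherits(x, "profile_matrix")) x$labels
                                 else rep("all", nrow(filled)),
                        var_names = model$var_names,
                        var_roles = if (inherits(x, "profile_matrix")) x$var_roles
                                    else NULL)
  if (is.null(scaler)) return(out)
  list(scaled = out, original = apply_scaler(scaler, out, inverse = TRUE))
}

#' Per-variable loading table for the first two components
#'
#' Export for biplot-style displays: one row per variable with its role and
#' its PC1/PC2 loadings under the model's canonical orientation (largest
#' |loading| of each component positive).
#'
#' @param model A fitted `ppca_model`.
#' @param var_names,var_roles Optional overrides; default to the model's.
#' @return A data frame with columns `variable`, `role`, `PC1` and (when
#'   `q >= 2`) `PC2`.
#' @export
loadings_report <- function(model, var_names = NULL, var_roles = NULL) {
  var_names <- var_names %||% model$var_names
  var_roles <- var_roles %||% model$var_roles %||% rep(NA_character_,
                                                       length(var_names))
  out <- data.frame(variable = var_names, role = var_roles,
                    PC1 = model$W[, 1], stringsAsFactors = FALSE)
  if (model$q >= 2) out$PC2 <- model$W[, 2]
  rownames(out) <- NULL
  out
}
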