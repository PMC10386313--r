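# Oracles: the eigendecomposition closed form on complete data, direct
# numerical likelihood maximisation on a tiny missing-data instance, and
# conditional-Gaussian formulas for scores and reconstruction.

test_that("complete-data fit matches the eigendecomposition closed form", {
  set.seed(42)
  W_true <- matrix(rnorm(6 * 2), 6, 2) %*% diag(c(3, 1.5))
  X <- ppca_sample(60, W_true, mu = rep(2, 6), sigma = 0.7, seed = 1)
  q <- 2
  fit <- fit_ppca(X, q, tol = 1e-12, max_iter = 5000)

  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / nrow(X)
  es <- eigen(S, symmetric = TRUE)
  sigma2_ml <- mean(es$values[(q + 1):6])
  W_ml <- es$vectors[, 1:q] %*% diag(sqrt(es$values[1:q] - sigma2_ml))

  ll_ml <- ll_direct(X, W_ml, mu, sigma2_ml)
  ll_em <- as.numeric(logLik(fit))
  expect_lt(abs(ll_em - ll_ml), 1e-6)
  # fitted subspace equals the classical PCA subspace
  expect_lt(subspace_angle(fit$W, es$vectors[, 1:q]), 1e-6)
  # and the rotated loadings satisfy the canonical form
  WtW <- crossprod(fit$W)
  expect_equal(WtW, diag(diag(WtW)), tolerance = 1e-8)
  expect_true(all(diff(diag(WtW)) <= 1e-8))
})

test_that("EM on a 6x3 instance with 2 missing cells attains the maximum of
           the observed-data likelihood", {
  set.seed(7)
  X <- ppca_sample(6, matrix(c(1.2, -0.8, 0.5), 3, 1), mu = c(0.5, -1, 2),
                   sigma = 0.4, seed = 2)
  X[2, 1] <- NA
  X[5, 3] <- NA
  fit <- fit_ppca(X, 1, tol = 1e-13, max_iter = 10000)
  ll_em <- as.numeric(logLik(fit))
  expect_equal(ll_em, ll_direct(X, fit$W, fit$mu, fit$sigma2),
               tolerance = 1e-8)

  # independent oracle: generic numerical maximisation over (W, mu, log s2)
  obj <- function(par) {
    if (exp(par[7]) < 1e-10) return(1e10)
    val <- tryCatch(-ll_direct(X, matrix(par[1:3], 3, 1), par[4:6],
                               exp(par[7])),
                    error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }
  set.seed(11)
  starts <- c(
    list(c(rnorm(3), colMeans(X, na.rm = TRUE), log(0.5))),
    lapply(1:4, function(i) c(rnorm(3), rnorm(3), rnorm(1)))
  )
  best <- min(vapply(starts, function(s) {
    stats::optim(s, obj, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))$value
  }, numeric(1)))
  ll_opt <- -best
  expect_lt(abs(ll_em - ll_opt), 1e-6)
})

test_that("noiseless collinear data drive sigma2 to zero and W to the line", {
  direction <- c(2, -1, 0.5) / sqrt(5.25)
  t_vals <- seq(-3, 3, length.out = 20)
  X <- outer(t_vals, direction) + matrix(c(1, 2, 3), 20, 3, byrow = TRUE)
  fit <- fit_ppca(X, 1, tol = 1e-13)
  expect_lt(fit$sigma2, 1e-6)
  expect_lt(subspace_angle(fit$W, matrix(direction)), 1e-6)
})

test_that("scores are the conditional-Gaussian posterior means", {
  set.seed(5)
  W <- matrix(rnorm(8 * 3), 8, 3)
  X <- ppca_sample(80, W, mu = rnorm(8), sigma = 0.5, seed = 6)
  fit <- fit_ppca(X, 3, tol = 1e-10)

  # a sample equal to mu, fully observed, scores at 0
  at_mu <- matrix(fit$mu, 1, 8)
  expect_equal(unname(ppca_scores(fit, at_mu)$scores), matrix(0, 1, 3),
               tolerance = 1e-12)

  # a fully missing sample scores at the prior mean
  empty <- matrix(NA_real_, 1, 8)
  expect_equal(unname(ppca_scores(fit, empty)$scores), matrix(0, 1, 3))

  # partial observation: direct formula from the joint covariance
  xnew <- X[1, ]
  xnew[c(2, 5, 7)] <- NA
  o <- which(!is.na(xnew))
  Co <- tcrossprod(fit$W[o, ]) + fit$sigma2 * diag(length(o))
  z_direct <- drop(t(fit$W[o, ]) %*% solve(Co, xnew[o] - fit$mu[o]))
  expect_equal(unname(drop(ppca_scores(fit, matrix(xnew, 1))$scores)), z_direct,
               tolerance = 1e-10)
})

test_that("reconstruction is the conditional mean and fixes observed cells", {
  set.seed(8)
  W <- matrix(rnorm(3 * 2), 3, 2)
  X <- ppca_sample(40, W, mu = c(1, -2, 0.5), sigma = 0.3, seed = 9)
  fit <- fit_ppca(X, 2, tol = 1e-10)

  # complete input is returned unchanged
  rec <- ppca_reconstruct(fit, X)
  expect_equal(unname(rec$values), unname(X), tolerance = 1e-12)
  expect_true(all(rec$mask))

  # fully missing sample reconstructs to mu
  empty <- matrix(NA_real_, 1, 3)
  expect_equal(unname(drop(ppca_reconstruct(fit, empty)$values)), unname(fit$mu))

  # one missing cell: direct conditional mean from the 3x3 model covariance
  xnew <- X[4, ]
  xnew[2] <- NA
  Sigma <- tcrossprod(fit$W) + fit$sigma2 * diag(3)
  o <- c(1, 3)
  cond <- fit$mu[2] +
    Sigma[2, o] %*% solve(Sigma[o, o], xnew[o] - fit$mu[o])
  got <- ppca_reconstruct(fit, matrix(xnew, 1))$values[1, 2]
  expect_equal(unname(got), drop(cond), tolerance = 1e-10)
})

test_that("the log-likelihood never decreases, with or without missing data", {
  set.seed(31)
  for (case in 1:4) {
    W <- matrix(rnorm(7 * 2), 7, 2)
    X <- ppca_sample(50, W, mu = rnorm(7), sigma = 0.8, seed = 30 + case)
    if (case > 1) {
      drop_idx <- sample(length(X), round(0.2 * length(X)))
      X[drop_idx] <- NA
    }
    fit <- fit_ppca(X, 2, tol = 1e-9)
    expect_monotone_ll(fit)
    expect_true(fit$converged)
  }
})

test_that("generating loadings and noise are recovered from generator output", {
  des <- study_design(complete_counts = c(250, 250, 250),
                      partial_counts = c(0, 0, 0))
  eff <- season_effects(des, seed = 11)
  pm <- generate_dataset(des, eff, seed = 12)
  fit <- fit_ppca(pm, eff$q_true, tol = 1e-9)
  expect_lt(subspace_angle(fit$W, eff$loadings_true), 0.1)
  expect_lt(abs(fit$sigma2 - eff$noise_sd^2) / eff$noise_sd^2, 0.15)
})

test_that("subspace error grows gracefully with the missing fraction", {
  des <- study_design(complete_counts = c(40, 40, 40),
                      partial_counts = c(0, 0, 0))
  angle_at <- function(frac) {
    mean(sapply(1:2, function(s) {
      eff <- season_effects(des, seed = s)
      pm <- generate_dataset(des, eff, seed = 10 + s)
      if (frac > 0) {
        pm <- apply_missing_pattern(pm, "random", fraction = frac,
                                    seed = 20 + s)
      }
      fit <- suppressWarnings(fit_ppca(pm, eff$q_true, tol = 1e-6,
                                       max_iter = 300))
      subspace_angle(fit$W, eff$loadings_true)
    }))
  }
  angles <- c(angle_at(0), angle_at(0.2), angle_at(0.45))
  expect_true(all(diff(angles) > 0))
})

test_that("loadings report has one row per variable with canonical signs", {
  pm <- default_pm()
  scaled <- apply_scaler(fit_scaler(pm), pm)
  fit <- fit_ppca(scaled, 3, tol = 1e-8)
  rep_df <- loadings_report(fit)
  expect_equal(nrow(rep_df), 81)
  expect_named(rep_df, c("variable", "role", "PC1", "PC2"))
  # sign convention: largest-|loading| entry of each component is positive
  expect_gt(rep_df$PC1[which.max(abs(rep_df$PC1))], 0)
  expect_gt(rep_df$PC2[which.max(abs(rep_df$PC2))], 0)
  # explained-variance fractions are descending, in [0, 1], and sum <= 1
  ev <- fit$explained_variance
  expect_true(all(ev >= 0 & ev <= 1))
  expect_true(all(diff(ev) <= 0))
  expect_lte(sum(ev), 1)
})

test_that("estimated loading signs track the construction at large n", {
  # a latent axis whose strongest variable is positively loaded: under the
  # canonical orientation, every strongly loaded variable keeps its sign
  set.seed(13)
  W <- cbind(c(3, 2, -1.5, 0.1, 1), c(0.2, -0.4, 0.3, 2.5, -1))
  X <- ppca_sample(4000, W, mu = rep(0, 5), sigma = 0.3, seed = 14)
  fit <- fit_ppca(X, 2, tol = 1e-9)
  strong <- abs(W[, 1]) > 0.5
  expect_equal(unname(sign(fit$W[strong, 1])), sign(W[strong, 1]))
})

test_that("fit validates q and variable observability", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_ppca(X, 4), "q")
  expect_error(fit_ppca(X, 0), "q")
  X[, 2] <- NA
  X[1, 2] <- 1
  expect_error(fit_ppca(X, 1), "at least 2 samples")
})
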