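# shared fixtures: tiny deterministic profile matrices and model-generated
# data used across the unit tests

# small fully observed profile matrix with two variable roles
tiny_pm <- function(n = 6, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n * 4, mean = 5), n, 4)
  colnames(vals) <- c("FAME_01", "FAME_02", "Ca", "Na")
  profile_matrix(vals, labels = rep(c("January", "April"), length.out = n))
}

# data drawn exactly from the PPCA model x = W z + mu + noise
ppca_sample <- function(n, W, mu, sigma, seed = 1) {
  set.seed(seed)
  p <- nrow(W)
  q <- ncol(W)
  Z <- matrix(rnorm(n * q), n, q)
  Z %*% t(W) + matrix(rnorm(n * p, 0, sigma), n, p) +
    matrix(mu, n, p, byrow = TRUE)
}

# direct (Woodbury-free) observed-data log-likelihood for small instances:
# per sample, the marginal normal over its observed coordinates
ll_direct <- function(X, W, mu, sigma2) {
  p <- ncol(X)
  ll <- 0
  for (i in seq_len(nrow(X))) {
    o <- which(!is.na(X[i, ]))
    Co <- tcrossprod(W[o, , drop = FALSE]) + sigma2 * diag(length(o))
    d <- X[i, o] - mu[o]
    ll <- ll - 0.5 * (length(o) * log(2 * pi) +
                        as.numeric(determinant(Co)$modulus) +
                        drop(d %*% solve(Co, d)))
  }
  ll
}

# a generated default-design dataset shared by several tests
default_pm <- function(seed = 7) generate_dataset(seed = seed)

expect_monotone_ll <- function(fit, tol = 1e-8) {
  d <- diff(fit$ll_trace)
  expect_true(all(d >= -tol * pmax(1, abs(fit$ll_trace[-1]))))
}
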