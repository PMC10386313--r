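# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All exported stochastic entry points route their
# randomness through this, so a single integer seed fixes a whole run.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# iteration-level sub-seeds derived from one master seed (kept < 2^31)
draw_seeds <- function(n) sample.int(2147483646L, n)

#' Largest principal angle between two column spaces
#'
#' Measures how far apart the subspaces spanned by the columns of `a` and `b`
#' are, in radians. Zero means identical spans; `pi/2` means some direction of
#' one space is orthogonal to all of the other. Used to compare an estimated
#' loading subspace with a reference (e.g. the generating loadings, or a
#' classical PCA solution).
#'
#' @param a,b Numeric matrices with the same number of rows; their columns
#'   span the subspaces to compare.
#' @return The largest principal angle in radians, a scalar in `[0, pi/2]`.
#' @examples
#' subspace_angle(diag(3)[, 1:2], diag(3)[, 1:2])      # 0
#' subspace_angle(diag(3)[, 1, drop = FALSE], diag(3)[, 3, drop = FALSE])
#' @export
subspace_angle <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("subspaces must live in the same ambient space")
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  d <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  acos(min(1, max(-1, min(d))))
}
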