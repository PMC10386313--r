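# Linear discriminant classification in latent-score space: minimal
# Mahalanobis distance to class centroids under a pooled within-class
# covariance and equal priors, which gives affine decision boundaries.

#' Fit a centroid/pooled-covariance linear discriminant model
#'
#' @param scores An n x q score matrix, or the list returned by
#'   [ppca_scores()].
#' @param labels Class labels of length n; the factor level order fixes the
#'   deterministic tie-break in [classify_lda()].
#' @return An object of class `mahal_lda` with `classes`, `centroids`
#'   (class x q) and `pooled_cov` (q x q).
#' @export
fit_lda <- function(scores, labels) {
  if (is.list(scores) && !is.data.frame(scores)) scores <- scores$scores
  scores <- as.matrix(scores)
  q <- ncol(scores)
  labels <- if (is.factor(labels)) droplevels(labels)
            else factor(labels, levels = unique(labels))
  if (length(labels) != nrow(scores)) stop("labels/scores length mismatch")
  classes <- levels(labels)
  k <- length(classes)
  if (k < 2) stop("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("every class needs at least 2 samples; offending: ",
         paste(classes[counts < 2], collapse = ", "))
  }
  n <- nrow(scores)
  if (n <= q + k) {
    stop("too few samples (", n, ") for ", q,
         " components and ", k, " classes; use fewer components")
  }
  centroids <- matrix(0, k, q, dimnames = list(classes, colnames(scores)))
  Spool <- matrix(0, q, q)
  for (c in seq_len(k)) {
    Xc <- scores[labels == classes[c], , drop = FALSE]
    centroids[c, ] <- colMeans(Xc)
    Spool <- Spool + crossprod(sweep(Xc, 2, centroids[c, ]))
  }
  Spool <- Spool / (n - k)
  ch <- tryCatch(chol(Spool), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-10)) {
    stop("pooled within-class covariance is singular; use fewer components")
  }
  structure(list(classes = classes, centroids = centroids,
                 pooled_cov = Spool, chol = ch, q = q),
            class = "mahal_lda")
}

#' Classify scores by minimal Mahalanobis distance
#'
#' Equal priors; ties broken deterministically by class order.
#'
#' @param model A `mahal_lda` model.
#' @param scores Score matrix (or [ppca_scores()] output) with the model's
#'   dimensionality.
#' @return Factor of predicted classes.
#' @export
classify_lda <- function(model, scores) {
  if (is.list(scores) && !is.data.frame(scores)) scores <- scores$scores
  scores <- as.matrix(scores)
  if (ncol(scores) != model$q) {
    stop("score dimension (", ncol(scores), ") does not match model (",
         model$q, ")")
  }
  d2 <- sapply(seq_along(model$classes), function(c) {
    stats::mahalanobis(scores, model$centroids[c, ], model$pooled_cov)
  })
  d2 <- matrix(d2, nrow = nrow(scores))
  idx <- max.col(-d2, ties.method = "first")
  factor(model$classes[idx], levels = model$classes)
}

#' Pairwise linear decision boundaries in the 2-component view
#'
#' For each class pair, the line `a x + b y + c = 0` on which the two
#' Mahalanobis distances are equal. Requires a model fitted on exactly two
#' components (the visualisation view).
#'
#' @param model A `mahal_lda` with `q = 2`.
#' @return Data frame with columns `class_i`, `class_j`, `a`, `b`, `c`.
#' @export
lda_boundaries_2d <- function(model) {
  if (model$q != 2) stop("boundaries_2d requires a model with 2 components")
  Sinv <- chol2inv(model$chol)
  pairs <- utils::combn(seq_along(model$classes), 2)
  out <- apply(pairs, 2, function(pr) {
    ci <- model$centroids[pr[1], ]
    cj <- model$centroids[pr[2], ]
    ab <- 2 * Sinv %*% (cj - ci)           # gradient of d_i^2 - d_j^2
    cc <- drop(ci %*% Sinv %*% ci - cj %*% Sinv %*% cj)
    c(a = ab[1], b = ab[2], c = cc)
  })
  data.frame(class_i = model$classes[pairs[1, ]],
             class_j = model$classes[pairs[2, ]],
             a = out["a", ], b = out["b", ], c = out["c", ],
             stringsAsFactors = FALSE)
}
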