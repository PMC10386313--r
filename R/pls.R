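# Partial least squares comparators. The predictor block is the fully
# observed mineral block (PLS cannot handle missing cells). NIPALS with
# deflation of both blocks; X and Y are autoscaled inside the fit using the
# calibration statistics, so predictions are returned on the original scale.

#' Fit a PLS regression model (NIPALS)
#'
#' Iterative latent-variable decomposition of autoscaled `X` and `Y` with
#' deflation of both blocks. At `n_lv = min(n - 1, ncol(X))` on full-rank
#' predictors the coefficients coincide with the ordinary least-squares
#' solution.
#'
#' @param X Predictor matrix, no missing cells.
#' @param Y Response matrix or vector, no missing cells.
#' @param n_lv Number of latent variables, `<= min(n - 1, ncol(X))`.
#' @return An object of class `pls_model` carrying the coefficient matrix
#'   `B` (on the autoscaled scale), scores/weights/loadings, and the
#'   centering/scaling records needed for prediction.
#' @export
fit_pls <- function(X, Y, n_lv) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- storage.mode(Y) <- "double"
  if (anyNA(X) || anyNA(Y)) {
    stop("PLS requires complete data; X/Y contain missing cells")
  }
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 3) stop("need at least 3 samples")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1 || n_lv > min(n - 1, ncol(X))) {
    stop("`n_lv` must be in [1, min(n - 1, ncol(X))] = [1, ",
         min(n - 1, ncol(X)), "]")
  }
  x_names <- colnames(X) %||% paste0("X", seq_len(ncol(X)))
  y_names <- colnames(Y) %||% paste0("Y", seq_len(ncol(Y)))

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale <= 0)) {
    stop("zero-variance predictor: ",
         paste(x_names[x_scale <= 0], collapse = ", "))
  }
  y_center <- colMeans(Y)
  y_scale <- apply(Y, 2, stats::sd)
  y_scale[y_scale <= 0] <- 1  # constant response column: centre only
  X0 <- sweep(sweep(X, 2, x_center), 2, x_scale, `/`)
  Y0 <- sweep(sweep(Y, 2, y_center), 2, y_scale, `/`)

  px <- ncol(X0)
  py <- ncol(Y0)
  Wmat <- matrix(0, px, n_lv)
  Pmat <- matrix(0, px, n_lv)
  Cmat <- matrix(0, py, n_lv)
  Tmat <- matrix(0, n, n_lv)
  n_used <- 0L
  for (a in seq_len(n_lv)) {
    u <- Y0[, which.max(apply(Y0, 2, stats::var))]
    if (sum(u^2) < 1e-12) u <- Y0[, 1]
    repeat {
      w <- drop(crossprod(X0, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      tt <- drop(X0 %*% w)
      cc <- drop(crossprod(Y0, tt)) / sum(tt^2)
      u_new <- drop(Y0 %*% cc) / sum(cc^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-12 * max(1, sqrt(sum(u^2)))) {
        u <- u_new
        break
      }
      u <- u_new
    }
    w <- drop(crossprod(X0, u))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10) break  # X block exhausted
    w <- w / nw
    tt <- drop(X0 %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-10) break
    pp <- drop(crossprod(X0, tt)) / tt2
    cc <- drop(crossprod(Y0, tt)) / tt2
    X0 <- X0 - tcrossprod(tt, pp)
    Y0 <- Y0 - tcrossprod(tt, cc)
    Wmat[, a] <- w
    Pmat[, a] <- pp
    Cmat[, a] <- cc
    Tmat[, a] <- tt
    n_used <- a
  }
  if (n_used == 0L) stop("no usable latent variable could be extracted")
  if (n_used < n_lv) {
    warning("X block exhausted after ", n_used, " latent variables")
    Wmat <- Wmat[, seq_len(n_used), drop = FALSE]
    Pmat <- Pmat[, seq_len(n_used), drop = FALSE]
    Cmat <- Cmat[, seq_len(n_used), drop = FALSE]
    Tmat <- Tmat[, seq_len(n_used), drop = FALSE]
  }
  B <- Wmat %*% solve(crossprod(Pmat, Wmat), t(Cmat))

  structure(list(B = B, n_lv = n_used, n_lv_requested = n_lv,
                 weights = Wmat, x_loadings = Pmat, y_loadings = Cmat,
                 scores = Tmat, x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 x_names = x_names, y_names = y_names),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Predictor matrix with the model's variables, no missing
#'   cells.
#' @param ... Ignored.
#' @return Predicted response matrix on the original response scale.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (anyNA(X)) {
    stop("PLS prediction requires complete predictor data (missing cells found)")
  }
  if (ncol(X) != length(object$x_center)) {
    stop("newdata has ", ncol(X), " predictors; model expects ",
         length(object$x_center))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), object$x_names)) {
    stop("predictor names do not match the fitted model")
  }
  X0 <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`)
  Y0 <- X0 %*% object$B
  out <- sweep(sweep(Y0, 2, object$y_scale, `*`), 2, object$y_center, `+`)
  colnames(out) <- object$y_names
  out
}

#' Fit a PLS-DA classifier
#'
#' PLS regression onto a one-hot class indicator matrix in `{0, 1}`;
#' prediction decodes by the argmax of the predicted indicators with a
#' deterministic tie-break by class order.
#'
#' @param X Predictor matrix, no missing cells.
#' @param labels Class labels of length `nrow(X)`.
#' @param n_lv Number of latent variables.
#' @return A `plsda_model` (inherits `pls_model`) with a `classes` field.
#' @export
fit_plsda <- function(X, labels, n_lv) {
  labels <- if (is.factor(labels)) droplevels(labels)
            else factor(labels, levels = unique(labels))
  classes <- levels(labels)
  if (length(classes) < 2) stop("need at least 2 classes")
  Y <- sapply(classes, function(cl) as.numeric(labels == cl))
  colnames(Y) <- classes
  model <- fit_pls(X, Y, n_lv)
  model$classes <- classes
  class(model) <- c("plsda_model", class(model))
  model
}

#' Predict classes (or indicator scores) from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Predictor matrix.
#' @param type `"class"` for decoded labels, `"response"` for the raw
#'   predicted indicator matrix.
#' @param ... Ignored.
#' @return Factor of predicted classes, or the indicator-score matrix.
#' @export
predict.plsda_model <- function(object, newdata, type = c("class", "response"),
                                ...) {
  type <- match.arg(type)
  Yhat <- predict.pls_model(object, newdata)
  if (type == "response") return(Yhat)
  idx <- max.col(Yhat, ties.method = "first")
  factor(object$classes[idx], levels = object$classes)
}
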