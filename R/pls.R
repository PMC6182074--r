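# Single-response partial least squares (PLS1) by NIPALS, with leave-one-out
# RMSECV for latent-variable selection.
#
# For one response, each NIPALS component is closed-form: no inner iteration
# is needed. Per component a:
#   w_a = X'y / ||X'y||          (unit weight vector)
#   t_a = X w_a                  (score)
#   p_a = X't_a / t_a't_a        (X loading)
#   q_a = y't_a / t_a't_a        (y loading)
# followed by deflation of both blocks, X <- X - t p', y <- y - t q.
# The coefficient vector on scaled predictors is b = W (P'W)^-1 q.

#' Fit a PLS1 model by NIPALS
#'
#' @param Xs scaled (mean-centred, unit-variance) predictor matrix, n by p.
#' @param ys scaled response vector, length n.
#' @param A number of latent variables, `1 <= A <= min(n - 1, p)`. If the
#'   response is exhausted before `A` components (residual covariance
#'   numerically zero), the model is truncated with a warning.
#' @return an object of class `pls1`: list with weight matrix `W` (p x A),
#'   X-loadings `P`, y-loadings `q`, scores `T` (n x A, mutually orthogonal
#'   columns), coefficients `b` on the scaled predictors, and cumulative
#'   percent variance explained `var_x_cum`, `var_y_cum`.
#' @export
fit_pls1 <- function(Xs, ys, A) {
  Xs <- as.matrix(Xs)
  ys <- as.numeric(ys)
  n <- nrow(Xs)
  p <- ncol(Xs)
  if (length(ys) != n) stop("nrow(Xs) must equal length(ys)")
  if (A < 1 || A > min(n - 1, p)) {
    stop(sprintf("A must lie in 1..%d", min(n - 1, p)))
  }
  X <- Xs
  y <- ys
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  ssy0 <- sum(ys^2)
  ssx0 <- sum(Xs^2)
  var_y <- var_x <- numeric(A)
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (a == 1L && nw < 1e-14) stop("X'y = 0: no covariance direction to extract")
    if (nw < 1e-12 * sqrt(ssx0 * ssy0 + 1)) {
      warning(sprintf("response exhausted after %d component(s); A truncated", a - 1L))
      break
    }
    w <- w / nw
    t <- drop(X %*% w)
    tt <- sum(t^2)
    pa <- drop(crossprod(X, t)) / tt
    qa <- sum(y * t) / tt
    X <- X - tcrossprod(t, pa)
    y <- y - t * qa
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- t
    q[a] <- qa
    var_y[a] <- 100 * (1 - sum(y^2) / ssy0)
    var_x[a] <- 100 * (1 - sum(X^2) / ssx0)
    a_done <- a
  }
  A <- a_done
  keep <- seq_len(A)
  W <- W[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]
  q <- q[keep]
  b <- drop(W %*% solve(crossprod(P, W), q))
  names(b) <- colnames(Xs)
  structure(
    list(W = W, P = P, q = q, T = Tm, b = b, A = A,
         var_x_cum = var_x[keep], var_y_cum = var_y[keep]),
    class = "pls1"
  )
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 model: %d latent variable(s), %d predictors\n",
              x$A, nrow(x$W)))
  cat(sprintf("  cumulative %% variance explained: X %.2f, y %.2f\n",
              x$var_x_cum[x$A], x$var_y_cum[x$A]))
  invisible(x)
}

#' Coefficients of a truncated PLS1 model
#'
#' NIPALS components are nested: the coefficient vector of the model using
#' only the first `a` latent variables is available from a fitted model
#' without refitting.
#'
#' @param object a `pls1` model.
#' @param a number of components to use (default: all).
#' @return coefficient vector on the scaled predictors.
#' @export
pls1_coefficients <- function(object, a = object$A) {
  stopifnot(inherits(object, "pls1"), a >= 1, a <= object$A)
  k <- seq_len(a)
  b <- drop(object$W[, k, drop = FALSE] %*%
              solve(crossprod(object$P[, k, drop = FALSE],
                              object$W[, k, drop = FALSE]),
                    object$q[k]))
  names(b) <- names(object$b)
  b
}

#' @export
coef.pls1 <- function(object, ...) object$b

#' Predict from a PLS1 model on the original response scale
#'
#' Applies the stored X autoscaling to the new raw rows, forms `ys_hat = Z b`,
#' and un-scales with the stored y parameters.
#'
#' @param object a `pls1` model.
#' @param newdata raw predictor matrix with the training columns.
#' @param x_scaling,y_scaling `scaled_block` objects from [autoscale()] fitted
#'   on the training X and (reciprocal) response.
#' @param a number of latent variables to use (default: all fitted).
#' @param ... unused.
#' @return predicted response on the original (e.g. reciprocal-CCL17) scale.
#' @export
predict.pls1 <- function(object, newdata, x_scaling, y_scaling,
                         a = object$A, ...) {
  Z <- apply_scaling(x_scaling, newdata)
  if (ncol(Z) != nrow(object$W)) {
    stop("newdata columns do not match the fitted predictors")
  }
  b <- pls1_coefficients(object, a)
  ysd <- y_scaling$sds[y_scaling$kept][1]
  ymu <- y_scaling$means[y_scaling$kept][1]
  drop(ymu + ysd * (Z %*% b))
}

#' Leave-one-out RMSECV curve for PLS1
#'
#' For each left-out sample the scaling parameters are refit on the remaining
#' n - 1 rows (no leakage; set `rescale_folds = FALSE` to mimic scale-once
#' behaviour), a model with `A_max` components is fitted, and the held-out
#' sample is predicted at every component count. Errors are expressed in the
#' full-data scaled-y convention so curves are comparable across `A`:
#' `RMSECV(A) = sqrt(mean(((y_j - yhat_{-j}(A)) / sd(y))^2))`.
#'
#' @param X_raw raw predictor matrix, n by p (n >= 3).
#' @param y_raw raw response vector (e.g. reciprocal CCL17).
#' @param A_max largest component count to evaluate; at most `min(n - 2, p)`.
#' @param rescale_folds refit the autoscaling inside each fold (default TRUE).
#' @return an object of class `cv_curve`: list with `rmsecv` (length `A_max`)
#'   and `A_max`.
#' @export
loo_rmsecv <- function(X_raw, y_raw, A_max = NULL, rescale_folds = TRUE) {
  X_raw <- as.matrix(X_raw)
  n <- nrow(X_raw)
  if (n < 3) stop("leave-one-out needs at least 3 samples")
  if (is.null(colnames(X_raw))) colnames(X_raw) <- paste0("V", seq_len(ncol(X_raw)))
  bound <- min(n - 2, ncol(X_raw))
  if (is.null(A_max)) A_max <- bound
  if (A_max < 1 || A_max > bound) stop(sprintf("A_max must lie in 1..%d", bound))
  ysd_full <- stats::sd(y_raw)
  sc_full <- if (!rescale_folds) suppressWarnings(autoscale(X_raw)) else NULL
  err <- matrix(NA_real_, n, A_max)
  for (j in seq_len(n)) {
    Xtr <- X_raw[-j, , drop = FALSE]
    ytr <- y_raw[-j]
    if (rescale_folds) {
      sc <- suppressWarnings(autoscale(Xtr))
      Zt <- sc$data
      znew <- apply_scaling(sc, X_raw[j, , drop = FALSE])
    } else {
      sc <- sc_full
      Zfull <- apply_scaling(sc, X_raw)
      Zt <- Zfull[-j, , drop = FALSE]
      znew <- Zfull[j, , drop = FALSE]
    }
    ymu <- mean(ytr)
    ysd <- stats::sd(ytr)
    fit <- fit_pls1(Zt, (ytr - ymu) / ysd, min(A_max, ncol(Zt)))
    for (a in seq_len(fit$A)) {
      yhat <- ymu + ysd * drop(znew %*% pls1_coefficients(fit, a))
      err[j, a] <- (y_raw[j] - yhat) / ysd_full
    }
    if (fit$A < A_max) err[j, (fit$A + 1):A_max] <- err[j, fit$A]
  }
  structure(list(rmsecv = sqrt(colMeans(err^2)), A_max = A_max),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("Leave-one-out RMSECV (scaled-y units):\n")
  print(round(stats::setNames(x$rmsecv, seq_along(x$rmsecv)), 4))
  invisible(x)
}

#' Select the number of latent variables from an RMSECV curve
#'
#' Rule `"final_drop"` quantifies "the last meaningful drop in prediction
#' error before the plateau": the largest `A` whose relative improvement over
#' the previous value, `(RMSECV(A-1) - RMSECV(A)) / RMSECV(A-1)`, is at least
#' `rel_tol`; if no step qualifies, `A = 1`. Rule `"min"` takes the argmin.
#' A manual `override` bypasses both (curve inspection remains the analyst's
#' prerogative).
#'
#' @param curve a `cv_curve` from [loo_rmsecv()] (or a bare numeric vector).
#' @param rule selection rule.
#' @param rel_tol relative-improvement threshold for `"final_drop"`.
#' @param override integer; return this component count unquestioned.
#' @return selected number of latent variables.
#' @export
select_n_components <- function(curve, rule = c("final_drop", "min"),
                                rel_tol = 0.02, override = NULL) {
  r <- if (inherits(curve, "cv_curve")) curve$rmsecv else as.numeric(curve)
  if (length(r) == 0) stop("empty RMSECV curve")
  if (!is.null(override)) {
    if (override < 1 || override > length(r)) stop("override out of range")
    return(as.integer(override))
  }
  rule <- match.arg(rule)
  if (rule == "min") return(which.min(r))
  if (length(r) == 1) return(1L)
  imp <- (r[-length(r)] - r[-1]) / r[-length(r)]
  ok <- which(imp >= rel_tol)
  if (length(ok) == 0) 1L else as.integer(max(ok) + 1L)
}
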