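#' Linear maximum-margin classifier
#'
#' L2-regularized linear classifier with squared hinge loss,
#' `0.5 ||w||^2 + cost * sum_i max(0, 1 - y_i (x_i w + b))^2`, minimized
#' with BFGS. The squared hinge is used because it is differentiable, which
#' makes the optimization deterministic and fast; at separable or
#' near-separable problems it yields the same maximum-margin solution family
#' as the standard hinge. The intercept is unpenalized.
#'
#' @param x n x d numeric training matrix.
#' @param y binary labels (any two values; internally mapped to -1/+1).
#' @param cost soft-margin cost parameter C (default 1).
#' @return Object of class `linear_svm` with `w`, `b`, `levels`.
#' @export
linear_svm <- function(x, y, cost = 1) {
  X <- as.matrix(x)
  lv <- sort(unique(as.character(y)))
  if (length(lv) != 2L) stop("linear_svm needs exactly two classes")
  yy <- ifelse(as.character(y) == lv[2], 1, -1)
  d <- ncol(X)
  obj <- function(par) {
    w <- par[1:d]; b <- par[d + 1]
    m <- 1 - yy * (X %*% w + b)
    m[m < 0] <- 0
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(par) {
    w <- par[1:d]; b <- par[d + 1]
    m <- 1 - yy * (drop(X %*% w) + b)
    act <- m > 0
    gm <- -2 * cost * (m[act] * yy[act])
    gw <- w + drop(crossprod(X[act, , drop = FALSE], gm))
    c(gw, sum(gm))
  }
  fit <- stats::optim(numeric(d + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  structure(list(w = fit$par[1:d], b = fit$par[d + 1], levels = lv,
                 converged = fit$convergence == 0),
            class = "linear_svm")
}

#' @describeIn linear_svm Predict class labels for new data.
#' @param object a fitted `linear_svm`.
#' @param newdata matrix of test rows.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  s <- drop(as.matrix(newdata) %*% object$w) + object$b
  object$levels[(s > 0) + 1L]
}
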