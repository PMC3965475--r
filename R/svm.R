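#' L2-norm (squared-hinge) support vector machine with Gaussian kernel
#'
#' Solves the primal kernel problem
#' \deqn{\min_{\beta, b} \tfrac12 \beta^\top K \beta +
#'   C \sum_i \max(0, 1 - y_i(K\beta + b)_i)^2}
#' by the finite-Newton active-set method: with the active set fixed, the
#' optimal coefficients solve a bordered regularised linear system
#' \eqn{(K_{AA} + I/(2C))\beta_A + b\,1 = y_A}, \eqn{1^\top \beta_A = 0};
#' the active set (margin violators) is then refreshed and the iteration
#' repeated until stable.  The squared hinge makes the problem strictly
#' convex and the solution deterministic — no randomised working-set
#' heuristics are involved.
#'
#' @param x numeric feature matrix (rows = subjects); standardise features
#'   before calling (\code{\link{fit_risk_model}} does this for you).
#' @param y labels: two-level factor or 0/1 vector; the second level / 1 is
#'   the positive class.
#' @param C soft-margin cost (default 1).
#' @param gamma Gaussian kernel parameter \eqn{k(u,v)=\exp(-\gamma\|u-v\|^2)};
#'   default \code{1/ncol(x)}.
#' @param max_iter active-set iteration cap.
#' @return object of class \code{l2svm} with the expansion coefficients,
#'   offset, active set and training data needed for prediction.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(80), 40)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' f <- l2svm(x, y)
#' auc <- roc_auc(predict(f, x), y)$auc
#' @export
l2svm <- function(x, y, C = 1, gamma = NULL, max_iter = 100L) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    bad <- colnames(x)[apply(is.na(x), 2, any)]
    stop("features contain missing values in column(s): ",
         paste(bad, collapse = ", "))
  }
  yy <- to_pm1(y)
  if (length(unique(yy)) < 2) stop("labels must contain both classes")
  if (min(table(yy)) < 2) stop("need at least 2 subjects per class")
  n <- nrow(x)
  gamma <- gamma %||% (1 / ncol(x))
  K <- rbf_kernel(x, x, gamma)
  A <- seq_len(n)            # start with every point margin-active
  beta_A <- NULL; b <- 0
  f <- rep(0, n)
  obj <- Inf
  for (it in seq_len(max_iter)) {
    nA <- length(A)
    M <- K[A, A, drop = FALSE] + diag(1 / (2 * C), nA)
    ## bordered system via Cholesky: M is positive definite
    R <- chol(M)
    z <- backsolve(R, forwardsolve(R, cbind(yy[A], 1), upper.tri = TRUE,
                                   transpose = TRUE))
    b <- sum(z[, 1]) / sum(z[, 2])
    beta_A <- z[, 1] - b * z[, 2]
    f <- drop(K[, A, drop = FALSE] %*% beta_A) + b
    newA <- which(yy * f < 1)
    if (length(newA) == 0) newA <- A  # fully separated: keep current set
    if (identical(newA, A)) break
    A <- newA
  }
  structure(list(x = x, beta = beta_A, b = b, active = A, gamma = gamma,
                 C = C, decision_train = f, y = yy, iterations = it),
            class = "l2svm")
}

to_pm1 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  ifelse(y > min(y), 1, -1)
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' @export
print.l2svm <- function(x, ...) {
  cat(sprintf(
    "L2 (squared-hinge) SVM: n = %d, active set %d, C = %g, gamma = %.3g\n",
    nrow(x$x), length(x$active), x$C, x$gamma))
  invisible(x)
}

#' @export
predict.l2svm <- function(object, newdata, ...) {
  Kx <- rbf_kernel(as.matrix(newdata),
                   object$x[object$active, , drop = FALSE], object$gamma)
  drop(Kx %*% object$beta) + object$b
}

#' Platt calibration of decision values to class probabilities
#'
#' Fits the sigmoid \eqn{P(y=1\mid f) = 1/(1+\exp(Af+B))} to decision values
#' by regularised maximum likelihood with smoothed targets
#' \eqn{t_+=(N_++1)/(N_++2)}, \eqn{t_-=1/(N_-+2)}, using Newton's method with
#' backtracking.  The fitted mapping is strictly monotone in the decision
#' value (A < 0 whenever the decision value is positively associated with
#' the event class).
#'
#' @param decision numeric decision values.
#' @param labels two-level factor or 0/1 outcomes.
#' @return object of class \code{platt} with slope \code{A} and offset
#'   \code{B}; use \code{predict()} to map decision values to probabilities
#'   in (0, 1).
#' @export
platt_calibrate <- function(decision, labels) {
  y <- to_pm1(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  if (stats::sd(decision) == 0)
    stop("degenerate decision values: constant score cannot be calibrated")
  n1 <- sum(y > 0); n0 <- sum(y < 0)
  t <- ifelse(y > 0, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  f <- decision
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  obj <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    d1 <- t - p                      # dF/dz per point
    g <- c(sum(d1 * f), sum(d1))
    w <- p * (1 - p)
    H <- matrix(c(sum(w * f * f) + 1e-12, sum(w * f),
                  sum(w * f), sum(w) + 1e-12), 2)
    step <- solve(H, g)
    s <- 1
    repeat {
      A2 <- A - s * step[1]; B2 <- B - s * step[2]
      v2 <- obj(A2, B2)
      if (v2 < val + 1e-4 * s * sum(-g * step) || s < 1e-10) break
      s <- s / 2
    }
    if (abs(val - v2) < 1e-12 && max(abs(c(A - A2, B - B2))) < 1e-10) {
      A <- A2; B <- B2; val <- v2; break
    }
    A <- A2; B <- B2; val <- v2
  }
  structure(list(A = A, B = B, value = val, iterations = it),
            class = "platt")
}

#' @export
print.platt <- function(x, ...) {
  cat(sprintf("Platt sigmoid: P = 1/(1+exp(%.4g f %+.4g))\n", x$A, x$B))
  invisible(x)
}

#' @export
predict.platt <- function(object, decision, ...) {
  p <- 1 / (1 + exp(object$A * decision + object$B))
  pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps)
}
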