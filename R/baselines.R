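#' One-vs-rest linear SVM classifier (naive baseline)
#'
#' Trains one binary hinge-loss sub-problem per class ("class k vs the
#' rest") with the shared dual-coordinate-descent core, predicting by
#' argmax of the class scores. Treats the ordinal labels as unordered —
#' the naive comparator for the ordinal-partitioning model.
#'
#' @inheritParams svmop
#' @return Object of class `ovr_model` with `family = "svc"`: `W` has one
#'   column per class.
#' @export
svc_ovr <- function(x, y = NULL, C = 1, P = NULL, bias = TRUE,
                    control = dcd_control()) {
  d <- as_xy(x, y, P)
  l <- ncol(d$X) + as.integer(bias)
  W <- matrix(0, l, d$P)
  states <- vector("list", d$P)
  for (k in seq_len(d$P)) {
    yb <- ifelse(d$y == k, 1, -1)
    st <- solve_dcd(binary_problem(d$X, yb, C = C, add_bias = bias), control)
    W[, k] <- st$w
    states[[k]] <- st[c("epochs", "converged", "violation", "degenerate")]
  }
  structure(list(W = W, P = d$P, C = C, bias = isTRUE(bias),
                 family = "svc", feature_names = d$feature_names,
                 states = states, call = match.call()),
            class = "ovr_model")
}

#' One-vs-rest ridge-penalized logistic regression (naive baseline)
#'
#' Per-class regularized logistic fits via [glmnet::glmnet()] (ridge
#' penalty, `lambda = 1/(nC)` so C plays the same cost role as in the SVM
#' baselines), predicting by argmax of the linear scores.
#'
#' @inheritParams svmop
#' @return Object of class `ovr_model` with `family = "lr"`.
#' @export
lr_ovr <- function(x, y = NULL, C = 1, P = NULL, bias = TRUE) {
  d <- as_xy(x, y, P)
  n <- nrow(d$X)
  lambda <- 1 / (n * C)
  l <- ncol(d$X)
  # glmnet requires >= 2 columns; pad a zero column for univariate input
  Xfit <- if (l == 1L) methods::cbind2(d$X, 0) else d$X
  W <- matrix(0, l + as.integer(bias), d$P)
  for (k in seq_len(d$P)) {
    yk <- as.integer(d$y == k)
    fit <- glmnet::glmnet(Xfit, yk, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE,
                          intercept = bias, thresh = 1e-10)
    beta <- as.numeric(fit$beta[, 1])[seq_len(l)]
    W[, k] <- if (bias) c(beta, fit$a0[1]) else beta
  }
  structure(list(W = W, P = d$P, C = C, bias = isTRUE(bias),
                 family = "lr", feature_names = d$feature_names,
                 states = NULL, call = match.call()),
            class = "ovr_model")
}

#' @export
predict.ovr_model <- function(object, newdata, type = c("rank", "scores"),
                              ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "ordinal_dataset")) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as_dgc(X)
  if (object$bias) X <- add_bias_col(X)
  s <- as.matrix(X %*% object$W)
  if (type == "scores") return(s)
  # argmax with ties broken toward the lower class index
  as.integer(max.col(s, ties.method = "first"))
}

#' @exportS3Method base::print
print.ovr_model <- function(x, ...) {
  cat("One-vs-rest", switch(x$family, svc = "linear SVM",
                            lr = "logistic regression", x$family),
      "baseline:", x$P, "classes, C =", format(x$C), "\n")
  invisible(x)
}

#' @export
coef.ovr_model <- function(object, ...) {
  W <- object$W
  rn <- object$feature_names
  if (is.null(rn)) rn <- paste0("x", seq_len(nrow(W) - as.integer(object$bias)))
  if (object$bias) rn <- c(rn, "(bias)")
  dimnames(W) <- list(rn, paste0("class", seq_len(ncol(W))))
  W
}

#' Rounded ridge regression (naive SVR-style baseline)
#'
#' Treats the ordinal labels as real responses and fits
#' `min_w 1/2 ||w||^2 + C sum_i (y_i - w'x_i)^2` in closed form (normal
#' equations with ridge term `1/(2C)`). Predictions are rounded half-up to
#' the nearest label and clipped to `[1, P]`.
#'
#' @inheritParams svmop
#' @param eps reserved for an epsilon-insensitive variant; the default
#'   squared loss ignores it.
#' @return Object of class `svr_model`.
#' @export
svr_rounded <- function(x, y = NULL, C = 1, P = NULL, bias = TRUE, eps = 0) {
  d <- as_xy(x, y, P)
  X <- d$X
  if (bias) X <- add_bias_col(X)
  A <- as.matrix(Matrix::crossprod(X)) + diag(1 / (2 * C), ncol(X))
  b <- as.numeric(Matrix::crossprod(X, d$y))
  w <- solve(A, b)
  structure(list(w = w, P = d$P, C = C, bias = isTRUE(bias), eps = eps,
                 family = "svr", feature_names = d$feature_names,
                 call = match.call()),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, type = c("rank", "response"),
                              ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "ordinal_dataset")) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as_dgc(X)
  if (object$bias) X <- add_bias_col(X)
  raw <- as.numeric(X %*% object$w)
  if (type == "response") return(raw)
  # round half-up, then clip into the label range
  as.integer(pmin(pmax(floor(raw + 0.5), 1), object$P))
}

#' @exportS3Method base::print
print.svr_model <- function(x, ...) {
  cat("Rounded ridge regression baseline: P =", x$P,
      ", C =", format(x$C), "\n")
  invisible(x)
}

#' @export
coef.svr_model <- function(object, ...) {
  w <- object$w
  rn <- object$feature_names
  if (is.null(rn)) rn <- paste0("x", seq_len(length(w) - as.integer(object$bias)))
  if (object$bias) rn <- c(rn, "(bias)")
  stats::setNames(w, rn)
}
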