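#' Binarize ordinal labels for the p-th partition
#'
#' The p-th sub-problem asks "is the rank greater than p?": labels become
#' +1 when `y > p` and -1 otherwise.
#'
#' @param y integer labels in `1..P`.
#' @param p partition index, `1 <= p <= P-1`.
#' @return numeric vector in \{-1, +1\}.
#' @examples
#' binarize_labels(1:5, p = 4)  # -1 -1 -1 -1 +1
#' @export
binarize_labels <- function(y, p) {
  stopifnot(p >= 1)
  ifelse(y > p, 1, -1)
}

as_xy <- function(x, y, P) {
  if (inherits(x, "ordinal_dataset")) {
    list(X = x$X, y = x$y, P = x$P, feature_names = x$feature_names)
  } else {
    X <- as_dgc(x)
    y <- as.integer(y)
    if (is.null(P)) P <- max(y)
    list(X = X, y = y, P = as.integer(P), feature_names = colnames(x))
  }
}

#' Fit an ordinal-partitioning SVM (SVMOP)
#'
#' Decomposes a P-class ordinal problem into P-1 binary linear-SVM
#' sub-problems ("is the rank greater than p?", p = 1..P-1), each trained
#' by dual coordinate descent with the same cost C, and stacks the learned
#' weight vectors into the l x (P-1) matrix W. Prediction joins the
#' sub-model scores with a counting rule (see [predict.svmop()]).
#'
#' A sub-problem can be single-class (no instance above rank p); it is then
#' trained in degenerate mode and a warning is recorded on the model.
#'
#' @param x an [ordinal_dataset()], or a numeric/sparse matrix of features.
#' @param y integer labels in `1..P` (ignored when `x` is a dataset).
#' @param C positive cost parameter shared by all sub-models; per-partition
#'   costs may be given as a vector of length P-1.
#' @param P number of ordered categories; defaults to `max(y)`.
#' @param bias augment a constant-1 feature in every sub-model
#'   (default `TRUE`; set `FALSE` for the pure homogeneous form).
#' @param prediction `"count"` (default): rank = 1 + number of positive
#'   scores; `"sequential"`: stop at the first non-positive score.
#' @param control a [dcd_control()].
#' @return Object of class `svmop`: list with `W` (weight matrix, one
#'   column per partition, including the bias row last when `bias = TRUE`),
#'   `P`, `C`, `bias`, `prediction`, `feature_names`, `states` (per-
#'   partition solver summaries), `warnings`, and the training call.
#' @examples
#' ds <- gen_ordinal(latent_threshold_spec(n = 200, l = 5, P = 4, seed = 1))
#' fit <- svmop(ds, C = 1)
#' fit
#' mean(abs(predict(fit, ds) - ds$y))
#' @export
svmop <- function(x, y = NULL, C = 1, P = NULL, bias = TRUE,
                  prediction = c("count", "sequential"),
                  control = dcd_control()) {
  prediction <- match.arg(prediction)
  d <- as_xy(x, y, P)
  if (d$P < 2L) stop("P must be >= 2")
  Cs <- if (length(C) == 1L) rep(C, d$P - 1L) else C
  if (length(Cs) != d$P - 1L) stop("C must have length 1 or P-1")
  l <- ncol(d$X) + as.integer(bias)
  W <- matrix(0, l, d$P - 1L)
  states <- vector("list", d$P - 1L)
  warns <- character(0)
  for (p in seq_len(d$P - 1L)) {
    yb <- binarize_labels(d$y, p)
    prob <- binary_problem(d$X, yb, C = Cs[p], add_bias = bias)
    st <- solve_dcd(prob, control)
    if (st$degenerate)
      warns <- c(warns, sprintf(
        "sub-problem p=%d is single-class (all labels %s); degenerate fit",
        p, if (yb[1] > 0) "> p" else "<= p"))
    W[, p] <- st$w
    states[[p]] <- st[c("epochs", "converged", "violation", "degenerate")]
  }
  for (wmsg in warns) warning(wmsg, call. = FALSE)
  structure(list(W = W, P = d$P, C = Cs, bias = isTRUE(bias),
                 prediction = prediction,
                 feature_names = d$feature_names,
                 states = states, warnings = warns,
                 control = control, call = match.call()),
            class = "svmop")
}

# scores s_p = w_p'x for all partitions; x may be a matrix/dataset
svmop_scores <- function(object, newdata) {
  X <- if (inherits(newdata, "ordinal_dataset")) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as_dgc(X)
  lw <- nrow(object$W) - as.integer(object$bias)
  if (ncol(X) != lw)
    stop("dimension mismatch: model has ", lw, " features, data has ", ncol(X))
  if (object$bias) X <- add_bias_col(X)
  as.matrix(X %*% object$W)
}

#' Decision scores of an ordinal-partitioning model
#'
#' Returns the raw sub-model scores `s_p = w_p' x` for each partition
#' p = 1..P-1. The bias column, when present, is appended automatically.
#'
#' @param object a fitted [svmop()] model.
#' @param newdata feature matrix, single feature vector, or
#'   [ordinal_dataset()].
#' @return numeric matrix, n x (P-1).
#' @export
decision_scores <- function(object, newdata) {
  stopifnot(inherits(object, "svmop"))
  svmop_scores(object, newdata)
}

#' Join partition scores into a rank
#'
#' The counting rule predicts `r(x) = 1 + #\{p : s_p > 0\}`: an instance's
#' rank is one plus the number of sub-models answering "yes, the rank
#' exceeds p". If no score is greater than 0 the rank is 1; if all are,
#' the rank is P. Ties at exactly 0 count as "not greater than 0". The
#' `sequential` rule instead stops at the first non-positive score:
#' `r(x) = 1 + max\{p : s_1..s_p all > 0\}`.
#'
#' @param scores numeric matrix n x (P-1) (or a single score vector).
#' @param rule `"count"` or `"sequential"`.
#' @return integer ranks in `1..P`.
#' @examples
#' rank_from_scores(c(-0.2, -1, -3, -0.5))        # 1
#' rank_from_scores(c(0.5, -0.1, 0.2, -0.3))      # 3 (count rule)
#' rank_from_scores(c(0.5, -0.1, 0.2, -0.3), rule = "sequential")  # 2
#' @export
rank_from_scores <- function(scores, rule = c("count", "sequential")) {
  rule <- match.arg(rule)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  pos <- scores > 0
  if (rule == "count") {
    as.integer(1L + rowSums(pos))
  } else {
    npos <- !pos
    first_fail <- apply(npos, 1L, function(z) {
      w <- which(z)
      if (length(w)) w[1] - 1L else length(z)
    })
    as.integer(1L + first_fail)
  }
}

#' Predict ordinal ranks
#'
#' @param object a fitted [svmop()] model.
#' @param newdata feature matrix, single feature vector, or
#'   [ordinal_dataset()].
#' @param type `"rank"` (default) for labels in `1..P`, `"scores"` for the
#'   raw P-1 decision scores.
#' @param rule override the model's prediction rule.
#' @param ... unused.
#' @return integer ranks, or a score matrix for `type = "scores"`.
#' @export
predict.svmop <- function(object, newdata, type = c("rank", "scores"),
                          rule = NULL, ...) {
  type <- match.arg(type)
  s <- svmop_scores(object, newdata)
  if (type == "scores") return(s)
  rank_from_scores(s, rule = if (is.null(rule)) object$prediction else rule)
}

#' @export
coef.svmop <- function(object, ...) {
  W <- object$W
  rn <- object$feature_names
  if (is.null(rn)) rn <- paste0("x", seq_len(nrow(W) - as.integer(object$bias)))
  if (object$bias) rn <- c(rn, "(bias)")
  dimnames(W) <- list(rn, paste0("rank>", seq_len(ncol(W))))
  W
}

#' @exportS3Method base::print
print.svmop <- function(x, ...) {
  cat("Ordinal-partitioning linear SVM (", x$P - 1L, " sub-models, P = ",
      x$P, ")\n", sep = "")
  cat("C:", paste(format(unique(x$C)), collapse = ", "),
      "  bias:", x$bias, "  prediction rule:", x$prediction, "\n")
  conv <- vapply(x$states, `[[`, TRUE, "converged")
  cat("Solver: ", sum(conv), "/", length(conv), " sub-models converged\n",
      sep = "")
  if (length(x$warnings)) cat("Warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.svmop <- function(object, ...) {
  st <- do.call(rbind, lapply(seq_along(object$states), function(p) {
    s <- object$states[[p]]
    data.frame(partition = p, epochs = s$epochs, converged = s$converged,
               violation = s$violation, degenerate = s$degenerate,
               w_norm = sqrt(sum(object$W[, p]^2)))
  }))
  structure(list(model = object, solver = st), class = "summary.svmop")
}

#' @exportS3Method base::print
print.summary.svmop <- function(x, ...) {
  print(x$model)
  cat("\nPer-partition solver state:\n")
  print(x$solver, row.names = FALSE)
  invisible(x)
}

#' Residuals of an ordinal-partitioning fit
#'
#' Signed rank errors `predicted - gold` on a dataset (training data must
#' be supplied; the model does not retain its design matrix).
#'
#' @param object a fitted [svmop()] model.
#' @param data an [ordinal_dataset()].
#' @param ... unused.
#' @return integer vector of signed rank errors.
#' @export
residuals.svmop <- function(object, data, ...) {
  stopifnot(inherits(data, "ordinal_dataset"))
  as.integer(predict(object, data)) - data$y
}

#' Plot per-feature contribution profile of an ordinal-partitioning model
#'
#' Bar plot of the weight-norm contributions Con_j (see
#' [feature_contribution()]) for the top `k` features.
#'
#' @param x a fitted [svmop()] model.
#' @param k number of features to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.svmop <- function(x, k = 20, ...) {
  imp <- feature_contribution(x)
  top <- utils::head(imp$ranking, k)
  nm <- if (!is.null(x$feature_names)) x$feature_names[top]
        else paste0("x", top)
  graphics::barplot(rev(imp$con[top]), names.arg = rev(nm), horiz = TRUE,
                    las = 1, xlab = "contribution ||W(j,:)||2", ...)
  invisible(x)
}
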