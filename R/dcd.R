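#' Solver control parameters for dual coordinate descent
#'
#' @param tol convergence tolerance: the maximum absolute projected-gradient
#'   violation over one full pass must fall to `tol` or below. Default 1e-3,
#'   the customary value for linear-SVM coordinate descent.
#' @param max_epochs maximum number of full passes over the data.
#' @param seed integer seed for the per-epoch coordinate permutation (the
#'   solver uses its own deterministic generator, independent of R's RNG).
#' @param shrinking enable the active-set shrinking heuristic. Off by
#'   default for auditability; when on, the returned weights agree with the
#'   unshrunk solution to within the tolerance.
#' @param loss `"l1"` (hinge, box constraint `0 <= alpha <= C`) or `"l2"`
#'   (squared hinge, unbounded alpha with a diagonal shift).
#' @return A list of class `dcd_control`.
#' @export
dcd_control <- function(tol = 1e-3, max_epochs = 1000L, seed = 1L,
                        shrinking = FALSE, loss = c("l1", "l2")) {
  loss <- match.arg(loss)
  stopifnot(tol > 0, max_epochs >= 1)
  structure(list(tol = tol, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), shrinking = isTRUE(shrinking),
                 loss = loss),
            class = "dcd_control")
}

#' Define one binary soft-margin SVM sub-problem
#'
#' The primal is `min_w 1/2 ||w||^2 + C sum_i max(0, 1 - yb_i w'x_i)`; the
#' slack variables are implicit in the hinge terms. The bias, when enabled,
#' is realized by augmenting every instance with a constant-1 feature.
#'
#' @param X numeric or sparse matrix, n x l.
#' @param yb binary labels in \{-1, +1\}.
#' @param C positive cost parameter multiplying the total hinge loss.
#' @param add_bias augment a constant-1 column (default `FALSE`: the
#'   sub-model form has no explicit intercept).
#' @return A list of class `binary_problem`.
#' @export
binary_problem <- function(X, yb, C = 1, add_bias = FALSE) {
  X <- as_dgc(X)
  yb <- as.numeric(yb)
  if (!all(yb %in% c(-1, 1))) stop("yb must be in {-1, +1}")
  if (nrow(X) != length(yb)) stop("nrow(X) != length(yb)")
  if (nrow(X) < 1L) stop("at least one instance required")
  if (C <= 0) stop("C must be > 0")
  if (add_bias) X <- add_bias_col(X)
  structure(list(X = X, yb = yb, C = C, add_bias = isTRUE(add_bias),
                 single_class = length(unique(yb)) == 1L),
            class = "binary_problem")
}

#' Solve a binary SVM sub-problem by dual coordinate descent
#'
#' Minimizes the dual `1/2 a'Qa - e'a` over the box `0 <= a_i <= C`
#' (squared-hinge: diagonal-shifted, unbounded above), one coordinate at a
#' time in a seeded random order per epoch, maintaining the primal weights
#' `w = sum_i a_i yb_i x_i` incrementally. Starts from `alpha = 0`.
#'
#' Instances whose feature row is entirely zero have constant dual gradient
#' -1; their optimal alpha is set analytically at the box edge and they are
#' excluded from the sweep (they cannot move `w`).
#'
#' A problem whose labels are all one class is well-posed but degenerate:
#' the solver proceeds normally (the returned `w` pushes every score toward
#' the common side) and the state is flagged `degenerate = TRUE`.
#'
#' @param prob a [binary_problem()].
#' @param control a [dcd_control()].
#' @param trace record per-epoch violation and dual objective (for
#'   convergence audits).
#' @return A list of class `dual_state`: `alpha`, `w`, `epochs`,
#'   `converged`, `violation`, `degenerate`, and optionally `trace`.
#' @export
solve_dcd <- function(prob, control = dcd_control(), trace = FALSE) {
  stopifnot(inherits(prob, "binary_problem"))
  Xt <- Matrix::t(prob$X)
  res <- .dcd_solve_cpp(Xt@p, Xt@i, Xt@x,
                        nrow(prob$X), ncol(prob$X), prob$yb, prob$C,
                        control$tol, control$max_epochs, control$seed,
                        control$loss == "l2", control$shrinking, trace)
  res$degenerate <- prob$single_class
  class(res) <- "dual_state"
  res
}

#' @exportS3Method base::print
print.dual_state <- function(x, ...) {
  cat("DCD dual state:", length(x$alpha), "dual variables,",
      x$epochs, "epochs,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(max violation %.3g)\n", x$violation))
  if (x$degenerate) cat("Degenerate: single-class problem\n")
  invisible(x)
}

#' Primal objective of a binary SVM sub-problem
#'
#' `1/2 ||w||^2 + C sum_i max(0, 1 - yb_i w'x_i)` for the L1 hinge
#' (squared hinge terms for `loss = "l2"`).
#'
#' @param prob a [binary_problem()].
#' @param w weight vector of length `ncol(prob$X)`.
#' @param loss `"l1"` or `"l2"`, matching the solver's loss.
#' @return scalar objective value.
#' @export
primal_objective <- function(prob, w, loss = c("l1", "l2")) {
  loss <- match.arg(loss)
  if (length(w) != ncol(prob$X)) stop("shape mismatch: length(w) != ncol(X)")
  margins <- prob$yb * as.numeric(prob$X %*% w)
  xi <- pmax(0, 1 - margins)
  if (loss == "l2") xi <- xi^2
  0.5 * sum(w^2) + prob$C * sum(xi)
}

#' Dual objective of a binary SVM sub-problem
#'
#' `e'a - 1/2 ||w(a)||^2` with `w(a) = sum_i a_i yb_i x_i` (squared hinge
#' subtracts the diagonal-shift term as well). By weak duality this never
#' exceeds [primal_objective()] at any feasible pair.
#'
#' @param prob a [binary_problem()].
#' @param state a `dual_state` (or a bare alpha vector).
#' @param loss `"l1"` or `"l2"`.
#' @return scalar objective value.
#' @export
dual_objective <- function(prob, state, loss = c("l1", "l2")) {
  loss <- match.arg(loss)
  alpha <- if (is.list(state)) state$alpha else state
  if (length(alpha) != nrow(prob$X)) stop("shape mismatch: length(alpha) != nrow(X)")
  w <- as.numeric(Matrix::crossprod(prob$X, alpha * prob$yb))
  val <- sum(alpha) - 0.5 * sum(w^2)
  if (loss == "l2") val <- val - sum(alpha^2) / (4 * prob$C)
  val
}
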