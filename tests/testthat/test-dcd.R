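test_that("two-point problem matches the closed-form solution", {
  # x1 = (1), y1 = +1; x2 = (-1), y2 = -1, C = 1, no bias: the dual
  # objective (a1 + a2) - (a1 + a2)^2 / 2 is maximized anywhere on the
  # segment a1 + a2 = 1 inside the box, so alpha itself is not unique;
  # the primal weight w = a1 + a2 = 1 and the dual value 1/2 are.
  prob <- binary_problem(matrix(c(1, -1), 2, 1), c(1, -1), C = 1)
  st <- solve_dcd(prob, dcd_control(tol = 1e-8, max_epochs = 10000))
  expect_equal(st$w, 1, tolerance = 1e-6)
  expect_equal(sum(st$alpha), 1, tolerance = 1e-6)
  expect_true(all(st$alpha >= 0 & st$alpha <= 1))
  expect_equal(dual_objective(prob, st), 0.5, tolerance = 1e-6)
  expect_true(st$converged)
})

test_that("solver matches the projected-gradient QP oracle on random problems", {
  set.seed(101)
  for (trial in 1:6) {
    n <- sample(5:25, 1); l <- sample(2:10, 1)
    C <- sample(c(0.1, 1, 10), 1)
    X <- matrix(rnorm(n * l), n)
    yb <- sample(c(-1, 1), n, replace = TRUE)
    prob <- binary_problem(X, yb, C = C)
    st <- solve_dcd(prob, dcd_control(tol = 1e-7, max_epochs = 50000,
                                      seed = trial))
    ref <- qp_svm_solve(X, yb, C)
    p_dcd <- primal_objective(prob, st$w)
    p_ref <- primal_objective(prob, ref$w)
    expect_equal(p_dcd, p_ref, tolerance = 1e-5)
  }
})

test_that("squared-hinge variant matches its QP oracle", {
  set.seed(202)
  X <- matrix(rnorm(15 * 4), 15)
  yb <- sample(c(-1, 1), 15, replace = TRUE)
  prob <- binary_problem(X, yb, C = 1)
  st <- solve_dcd(prob, dcd_control(tol = 1e-8, max_epochs = 50000,
                                    loss = "l2"))
  ref <- qp_svm_solve(X, yb, C = 1, l2 = TRUE)
  expect_equal(primal_objective(prob, st$w, loss = "l2"),
               primal_objective(prob, ref$w, loss = "l2"),
               tolerance = 1e-5)
  expect_true(all(st$alpha >= 0))
})

test_that("dual state invariants hold: box, w-alpha consistency, monotone dual", {
  set.seed(7)
  for (trial in 1:5) {
    X <- matrix(rnorm(20 * 6), 20)
    yb <- sample(c(-1, 1), 20, replace = TRUE)
    C <- c(0.1, 1, 10)[1 + trial %% 3]
    prob <- binary_problem(X, yb, C = C)
    st <- solve_dcd(prob, dcd_control(tol = 1e-6, max_epochs = 20000,
                                      seed = trial), trace = TRUE)
    expect_true(all(st$alpha >= -1e-12 & st$alpha <= C + 1e-12))
    # incremental w equals its from-scratch recomputation
    w_scratch <- as.numeric(t(as.matrix(X)) %*% (st$alpha * yb))
    expect_equal(st$w, w_scratch, tolerance = 1e-10)
    # per-epoch dual objective never decreases
    expect_true(all(diff(st$trace$dual_objective) >= -1e-10))
    # weak duality and tolerance-driven gap at convergence
    p <- primal_objective(prob, st$w)
    d <- dual_objective(prob, st)
    expect_gte(p, d - 1e-10)
    expect_lte(p - d, 1e-3 * (1 + abs(p)))
  }
})

test_that("dual objective is non-decreasing after every coordinate update", {
  # audited on the pure-R mirror of the algorithm (per-update recording)
  set.seed(33)
  X <- matrix(rnorm(12 * 3), 12)
  yb <- sample(c(-1, 1), 12, replace = TRUE)
  ref <- dcd_reference(X, yb, C = 1, epochs = 20)
  expect_true(all(diff(ref$dual_objectives) >= -1e-12))
  # and the mirror agrees with the compiled solver at convergence
  prob <- binary_problem(X, yb, C = 1)
  st <- solve_dcd(prob, dcd_control(tol = 1e-8, max_epochs = 20000))
  expect_equal(dual_objective(prob, st), dual_objective(prob, ref$alpha),
               tolerance = 1e-5)
})

test_that("trivial objective values: w = 0 and alpha = 0", {
  X <- matrix(rnorm(10 * 3), 10)
  prob <- binary_problem(X, rep(c(1, -1), 5), C = 2)
  expect_equal(primal_objective(prob, rep(0, 3)), 2 * 10)
  expect_equal(dual_objective(prob, rep(0, 10)), 0)
  expect_error(primal_objective(prob, rep(0, 5)), "shape mismatch")
  expect_error(dual_objective(prob, rep(0, 3)), "shape mismatch")
})

test_that("all-zero feature rows get alpha fixed at C without moving w", {
  X <- rbind(c(1, 0), c(0, 0), c(-1, 1))
  prob <- binary_problem(X, c(1, 1, -1), C = 0.7)
  st <- solve_dcd(prob, dcd_control(tol = 1e-8, max_epochs = 10000))
  expect_equal(st$alpha[2], 0.7)
  w_scratch <- as.numeric(t(X) %*% (st$alpha * prob$yb))
  expect_equal(st$w, w_scratch, tolerance = 1e-10)
})

test_that("single-class input is flagged degenerate yet solved correctly", {
  set.seed(71)
  X <- matrix(rnorm(8 * 3), 8)
  prob <- binary_problem(X, rep(1, 8), C = 1)
  st <- expect_silent(solve_dcd(prob, dcd_control(tol = 1e-7,
                                                  max_epochs = 50000)))
  expect_true(st$degenerate)
  # still the correct optimum of the (one-sided) hinge problem
  ref <- qp_svm_solve(X, rep(1, 8), C = 1)
  expect_equal(primal_objective(prob, st$w),
               primal_objective(prob, ref$w), tolerance = 1e-5)
  # the weight vector leans toward the common side: most margins positive
  expect_gte(mean(as.numeric(as.matrix(X) %*% st$w) > 0), 0.5)
})

test_that("feature/cost rescaling leaves decision signs unchanged", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30)
  yb <- sample(c(-1, 1), 30, replace = TRUE)
  cc <- 3
  st1 <- solve_dcd(binary_problem(X, yb, C = 1),
                   dcd_control(tol = 1e-8, max_epochs = 50000))
  st2 <- solve_dcd(binary_problem(cc * X, yb, C = 1 / cc^2),
                   dcd_control(tol = 1e-8, max_epochs = 50000))
  s1 <- sign(as.numeric(as.matrix(X) %*% st1$w))
  s2 <- sign(as.numeric(as.matrix(cc * X) %*% st2$w))
  expect_identical(s1, s2)
})

test_that("shrinking changes the solution by no more than the tolerance", {
  set.seed(12)
  X <- matrix(rnorm(60 * 5), 60)
  yb <- sample(c(-1, 1), 60, replace = TRUE)
  prob <- binary_problem(X, yb, C = 1)
  ctl_off <- dcd_control(tol = 1e-6, max_epochs = 50000, shrinking = FALSE)
  ctl_on <- dcd_control(tol = 1e-6, max_epochs = 50000, shrinking = TRUE)
  w_off <- solve_dcd(prob, ctl_off)$w
  w_on <- solve_dcd(prob, ctl_on)$w
  expect_equal(w_on, w_off, tolerance = 1e-4)
})

test_that("problem construction validates its inputs", {
  X <- matrix(1:4, 2)
  expect_error(binary_problem(X, c(0, 1)), "\\{-1, \\+1\\}")
  expect_error(binary_problem(X, c(1, -1), C = 0), "C must be > 0")
  expect_error(binary_problem(X, c(1, -1, 1)), "nrow")
  expect_error(dcd_control(tol = 0))
  expect_error(dcd_control(max_epochs = 0))
})
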