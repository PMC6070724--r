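# Independent oracles used across the suite. None of these share code with
# the package implementation paths they check.

# Box-constrained QP oracle: minimize 1/2 a'Qa - e'a over 0 <= a <= U by
# accelerated projected gradient (FISTA). An algorithm deliberately
# different from coordinate descent.
qp_box_solve <- function(Q, U, max_iter = 50000L, tol = 1e-12) {
  n <- nrow(Q)
  L <- max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 1e-12)
  proj <- function(a) pmin(pmax(a, 0), U)
  a <- rep(0, n)
  z <- a
  t_k <- 1
  for (it in seq_len(max_iter)) {
    g <- as.numeric(Q %*% z) - 1
    a_new <- proj(z - g / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- a_new + ((t_k - 1) / t_new) * (a_new - a)
    if (max(abs(a_new - a)) < tol && it > 10L) { a <- a_new; break }
    a <- a_new
    t_k <- t_new
  }
  a
}

# Reference solution of one hinge-SVM sub-problem through the dual QP,
# returning the primal weights via w = sum_i a_i y_i x_i.
qp_svm_solve <- function(X, yb, C, l2 = FALSE) {
  X <- as.matrix(X)
  K <- X %*% t(X)
  Q <- (yb %*% t(yb)) * K
  if (l2) {
    diag(Q) <- diag(Q) + 1 / (2 * C)
    U <- 1e9
  } else U <- C
  a <- qp_box_solve(Q, U)
  list(alpha = a, w = as.numeric(t(X) %*% (a * yb)))
}

# Pure-R mirror of cyclic dual coordinate descent, recording the dual
# objective after every single-coordinate update (for monotonicity audits).
dcd_reference <- function(X, yb, C, epochs = 50L) {
  X <- as.matrix(X)
  n <- nrow(X); l <- ncol(X)
  alpha <- rep(0, n)
  w <- rep(0, l)
  Qii <- rowSums(X^2)
  dual <- function() sum(alpha) - 0.5 * sum(w^2)
  objs <- dual()
  for (ep in seq_len(epochs)) {
    for (i in seq_len(n)) {
      if (Qii[i] == 0) next
      G <- yb[i] * sum(w * X[i, ]) - 1
      a_new <- min(max(alpha[i] - G / Qii[i], 0), C)
      w <- w + (a_new - alpha[i]) * yb[i] * X[i, ]
      alpha[i] <- a_new
      objs <- c(objs, dual())
    }
  }
  list(alpha = alpha, w = w, dual_objectives = objs)
}

# Quadratic-time pairwise-accuracy oracle.
pacc_bruteforce <- function(gold, pred, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  n <- length(gold)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (gold[i] > gold[j]) {
      den <- den + 1
      if (pred[i] > pred[j]) num <- num + 1
      else if (ties == "half" && pred[i] == pred[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("undefined")
  num / den
}

# Exhaustive longest-match, non-overlapping dictionary-count oracle: scan
# positions left to right, trying every term by brute force at each one.
dict_count_oracle <- function(text, terms) {
  n <- nchar(text)
  count <- 0L
  i <- 1L
  while (i <= n) {
    best <- 0L
    for (tm in terms) {
      L <- nchar(tm)
      if (L > best && i + L - 1L <= n &&
          substr(text, i, i + L - 1L) == tm) best <- L
    }
    if (best > 0L) { count <- count + 1L; i <- i + best } else i <- i + 1L
  }
  count
}

# Hand-rolled dense TF-IDF for tiny corpora (raw tf, smoothed idf,
# L2-normalized rows), computed entry by entry.
tfidf_oracle <- function(corpus, terms, df, n_docs) {
  M <- matrix(0, length(corpus), length(terms))
  for (d in seq_along(corpus)) {
    toks <- corpus[[d]]
    grams <- c(toks, if (length(toks) >= 2)
      paste(toks[-length(toks)], toks[-1], sep = "_"))
    for (j in seq_along(terms)) {
      tf <- sum(grams == terms[j])
      idf <- log((1 + n_docs) / (1 + df[j])) + 1
      M[d, j] <- tf * idf
    }
    nrm <- sqrt(sum(M[d, ]^2))
    if (nrm > 0) M[d, ] <- M[d, ] / nrm
  }
  M
}

# total hinge loss of a weight vector on a (possibly bias-augmented) problem
hinge_total <- function(prob, w) {
  sum(pmax(0, 1 - prob$yb * as.numeric(prob$X %*% w)))
}

# small random sparse dataset for round-trip tests; every class occurs so
# the reader's order-preserving label remap is the identity
random_sparse_dataset <- function(n, l, P, seed, density = 0.4) {
  set.seed(seed)
  stopifnot(n >= P)
  X <- Matrix::rsparsematrix(n, l, density)
  y <- sample(c(seq_len(P), sample.int(P, n - P, replace = TRUE)))
  ordinal_dataset(X, y, P = P)
}
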