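#' Gradient-boosted regression trees with leaf encoding
#'
#' Squared-loss gradient boosting over a small dense feature block (here,
#' the 8 customized consultation features): round m fits an axis-aligned
#' regression tree to the current residuals `y - F_{m-1}(x)` — the negative
#' gradient of the squared loss — and `F_m = F_{m-1} + lr * tree_m`. Split
#' search is exact greedy variance reduction over all unique thresholds,
#' with ties broken toward the lowest feature index then lowest threshold.
#' Besides regression predictions, the ensemble exposes the identity of
#' the leaf each instance reaches in each tree; one-hot encoding those
#' memberships yields "feature combination" columns for a downstream
#' linear model.
#'
#' @param x numeric matrix (n x d), dense.
#' @param y numeric response (ordinal labels cast to reals).
#' @param rounds number of boosting rounds M (>= 1).
#' @param depth maximum tree depth (a stump has depth 1).
#' @param learning_rate shrinkage in (0, 1].
#' @param min_leaf minimum instances per leaf.
#' @return object of class `gbdt`: `init` (the mean response), `trees`,
#'   `n_leaves` (per tree), `learning_rate`, `train_loss` (MSE after each
#'   round, non-increasing).
#' @export
gbdt <- function(x, y, rounds = 100L, depth = 3L, learning_rate = 0.1,
                 min_leaf = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L, rounds >= 1L,
            learning_rate > 0, learning_rate <= 1)
  init <- mean(y)
  Fx <- rep(init, length(y))
  trees <- vector("list", rounds)
  n_leaves <- integer(rounds)
  loss <- numeric(rounds)
  for (m in seq_len(rounds)) {
    res <- y - Fx
    tr <- grow_tree(x, res, depth = depth, min_leaf = min_leaf)
    trees[[m]] <- tr
    n_leaves[m] <- sum(is.na(tr$feature))
    Fx <- Fx + learning_rate * tree_predict(tr, x)$value
    loss[m] <- mean((y - Fx)^2)
  }
  structure(list(init = init, trees = trees, n_leaves = n_leaves,
                 learning_rate = learning_rate, rounds = rounds,
                 depth = depth, train_loss = loss,
                 d = ncol(x), call = match.call()),
            class = "gbdt")
}

# Grow one regression tree on (x, r) by exact greedy variance reduction.
# Nodes are rows of a data.frame: feature/threshold (NA at leaves),
# left/right child ids, value (leaf mean), leaf_id (NA at internal nodes).
grow_tree <- function(x, r, depth, min_leaf) {
  nodes <- list()
  leaf_counter <- 0L
  build <- function(idx, d) {
    node_id <- length(nodes) + 1L
    nodes[node_id] <<- list(NULL)  # reserve the slot before recursing
    sp <- if (d < depth && length(idx) >= 2L * min_leaf)
      best_split(x[idx, , drop = FALSE], r[idx], min_leaf) else NULL
    if (is.null(sp)) {
      leaf_counter <<- leaf_counter + 1L
      nodes[[node_id]] <<- list(feature = NA_integer_,
                                threshold = NA_real_,
                                left = NA_integer_, right = NA_integer_,
                                value = mean(r[idx]),
                                leaf_id = leaf_counter)
      return(node_id)
    }
    go_left <- x[idx, sp$feature] <= sp$threshold
    left_id <- build(idx[go_left], d + 1L)
    right_id <- build(idx[!go_left], d + 1L)
    nodes[[node_id]] <<- list(feature = sp$feature,
                              threshold = sp$threshold,
                              left = left_id, right = right_id,
                              value = NA_real_, leaf_id = NA_integer_)
    node_id
  }
  build(seq_along(r), 0L)
  do.call(rbind, lapply(nodes, as.data.frame))
}

# Best (feature, threshold) by variance reduction; NULL when no split
# strictly reduces the summed squared error. Candidate thresholds are the
# midpoints between consecutive distinct feature values.
best_split <- function(xs, rs, min_leaf) {
  n <- length(rs)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  parent <- sse(rs)
  best <- NULL
  best_gain <- 1e-12
  for (f in seq_len(ncol(xs))) {
    o <- order(xs[, f])
    xv <- xs[o, f]; rv <- rs[o]
    cs <- cumsum(rv); cs2 <- cumsum(rv^2)
    tot <- cs[n]; tot2 <- cs2[n]
    # split after position k (left = 1..k) only where the value changes
    ks <- which(diff(xv) > 0)
    ks <- ks[ks >= min_leaf & (n - ks) >= min_leaf]
    for (k in ks) {
      sse_l <- cs2[k] - cs[k]^2 / k
      sse_r <- (tot2 - cs2[k]) - (tot - cs[k])^2 / (n - k)
      gain <- parent - sse_l - sse_r
      # features and thresholds are visited in ascending order, so strict
      # improvement keeps the lowest feature index / lowest threshold on ties
      if (gain > best_gain + 1e-12) {
        best <- list(feature = f, threshold = (xv[k] + xv[k + 1]) / 2)
        best_gain <- gain
      }
    }
  }
  best
}

# route rows through one tree; returns leaf values and leaf ids
tree_predict <- function(tree, x) {
  n <- nrow(x)
  value <- numeric(n)
  leaf <- integer(n)
  recurse <- function(idx, node_id) {
    nd <- tree[node_id, ]
    if (is.na(nd$feature)) {
      value[idx] <<- nd$value
      leaf[idx] <<- nd$leaf_id
      return(invisible(NULL))
    }
    go_left <- x[idx, nd$feature] <= nd$threshold
    if (any(go_left)) recurse(idx[go_left], nd$left)
    if (any(!go_left)) recurse(idx[!go_left], nd$right)
  }
  if (n > 0) recurse(seq_len(n), 1L)
  list(value = value, leaf = leaf)
}

#' Leaf membership indices of a boosted ensemble
#'
#' @param model a fitted [gbdt()].
#' @param x feature matrix.
#' @return integer matrix n x M; entry (i, m) is the leaf (1-based within
#'   tree m) that row i reaches.
#' @export
leaf_indices <- function(model, x) {
  stopifnot(inherits(model, "gbdt"))
  x <- as.matrix(x)
  if (ncol(x) != model$d) stop("feature count mismatch")
  vapply(model$trees, function(tr) tree_predict(tr, x)$leaf,
         integer(nrow(x)))
}

#' One-hot leaf encoding of a boosted ensemble
#'
#' @param model a fitted [gbdt()].
#' @param x feature matrix.
#' @return sparse `dgCMatrix` with one column block per tree (width = total
#'   leaf count) and exactly M ones per row; columns named
#'   `gbdt_t{m}_leaf{j}`.
#' @export
encode_leaves <- function(model, x) {
  L <- leaf_indices(model, x)
  if (is.null(dim(L))) L <- matrix(L, nrow = 1)
  offsets <- cumsum(c(0L, model$n_leaves[-length(model$n_leaves)]))
  width <- sum(model$n_leaves)
  n <- nrow(L)
  jj <- as.integer(sweep(L, 2, offsets, "+"))
  M <- Matrix::sparseMatrix(i = rep.int(seq_len(n), model$rounds), j = jj,
                            x = 1, dims = c(n, width))
  colnames(M) <- unlist(lapply(seq_len(model$rounds), function(m)
    paste0("gbdt_t", m, "_leaf", seq_len(model$n_leaves[m]))))
  M
}

#' @export
predict.gbdt <- function(object, newdata,
                         type = c("response", "leaf", "onehot"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (type == "leaf") return(leaf_indices(object, x))
  if (type == "onehot") return(encode_leaves(object, x))
  if (ncol(x) != object$d) stop("feature count mismatch")
  pred <- rep(object$init, nrow(x))
  for (tr in object$trees)
    pred <- pred + object$learning_rate * tree_predict(tr, x)$value
  pred
}

#' @exportS3Method base::print
print.gbdt <- function(x, ...) {
  cat("Gradient-boosted regression trees:", x$rounds, "rounds, depth",
      x$depth, ", lr", x$learning_rate, "\n")
  cat(sprintf("Total leaves: %d   training MSE: %.4f -> %.4f\n",
              sum(x$n_leaves), x$train_loss[1],
              x$train_loss[length(x$train_loss)]))
  invisible(x)
}
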