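#' Mean absolute error between gold and predicted ranks
#'
#' @param gold,pred equal-length numeric label vectors.
#' @return mean of `|gold - pred|`.
#' @export
mae <- function(gold, pred) {
  check_pair(gold, pred)
  mean(abs(gold - pred))
}

#' Mean squared error between gold and predicted ranks
#'
#' @param gold,pred equal-length numeric label vectors.
#' @return mean of `(gold - pred)^2`.
#' @export
mse <- function(gold, pred) {
  check_pair(gold, pred)
  mean((gold - pred)^2)
}

check_pair <- function(gold, pred) {
  if (length(gold) != length(pred)) stop("gold and pred lengths differ")
  if (length(gold) == 0L) stop("empty input")
  invisible(NULL)
}

#' Pairwise accuracy (concordance) between gold and predicted ranks
#'
#' Over the preference set `S = \{(i, j) : gold_i > gold_j\}`, the fraction
#' of pairs whose predictions agree in direction (`pred_i > pred_j`). With
#' `ties = "strict"` (default) a tied prediction on an ordered gold pair
#' counts as discordant; `ties = "half"` gives such pairs half credit, the
#' concordance-index convention.
#'
#' Computed from the (gold x pred) contingency table, so it is exact and
#' O(n + P^2 * P'^2) rather than O(n^2).
#'
#' @param gold,pred equal-length integer label vectors.
#' @param ties `"strict"` or `"half"`.
#' @return fraction in `[0, 1]`; errors when all gold labels are equal
#'   (the denominator `|S|` is empty).
#' @examples
#' pacc(c(1, 2, 3), c(1, 3, 2))  # 2/3
#' @export
pacc <- function(gold, pred, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  check_pair(gold, pred)
  tab <- table(gold, pred)
  g_lev <- as.numeric(rownames(tab))
  p_lev <- as.numeric(colnames(tab))
  if (length(g_lev) < 2L) stop("PAcc undefined: all gold labels equal")
  ng <- length(g_lev); np <- length(p_lev)
  total <- 0; conc <- 0; tied <- 0
  for (a in seq_len(ng)) for (b in seq_len(ng)) {
    if (g_lev[a] <= g_lev[b]) next
    for (u in seq_len(np)) for (v in seq_len(np)) {
      m <- tab[a, u] * tab[b, v]
      if (m == 0) next
      total <- total + m
      if (p_lev[u] > p_lev[v]) conc <- conc + m
      else if (p_lev[u] == p_lev[v]) tied <- tied + m
    }
  }
  if (ties == "half") (conc + 0.5 * tied) / total else conc / total
}

#' Confusion matrix with adjacency mass
#'
#' @param gold,pred integer labels in `1..P`.
#' @param P number of categories.
#' @return list of class `ordinal_confusion`: `counts` (P x P, rows =
#'   gold), `proportions` (row-normalized), and `adjacent_share`, the
#'   fraction of off-diagonal (error) mass lying in classes adjacent to
#'   the truth — the "errors stay close" statistic of ordinal models.
#' @export
confusion <- function(gold, pred, P = max(gold, pred)) {
  check_pair(gold, pred)
  if (any(gold < 1 | gold > P) || any(pred < 1 | pred > P))
    stop("labels out of range [1, P]")
  counts <- matrix(0L, P, P, dimnames = list(gold = 1:P, pred = 1:P))
  for (i in seq_along(gold))
    counts[gold[i], pred[i]] <- counts[gold[i], pred[i]] + 1L
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  err <- counts
  diag(err) <- 0L
  n_err <- sum(err)
  adj <- if (n_err == 0) NA_real_ else {
    a <- 0L
    for (t in 1:P) {
      if (t > 1) a <- a + err[t, t - 1]
      if (t < P) a <- a + err[t, t + 1]
    }
    a / n_err
  }
  structure(list(counts = counts, proportions = props,
                 adjacent_share = adj),
            class = "ordinal_confusion")
}

#' @exportS3Method base::print
print.ordinal_confusion <- function(x, digits = 3, ...) {
  cat("Confusion matrix (rows = gold):\n")
  print(x$counts)
  cat("\nRow-normalized proportions:\n")
  print(round(x$proportions, digits))
  if (!is.na(x$adjacent_share))
    cat(sprintf("\nAdjacent-class share of errors: %.3f\n", x$adjacent_share))
  invisible(x)
}

#' Evaluate ordinal predictions
#'
#' Bundles the three ordinal metrics (MAE, MSE, pairwise accuracy) and the
#' confusion matrix into one report.
#'
#' @param gold,pred integer labels in `1..P`.
#' @param P number of categories.
#' @param ties tie convention for [pacc()].
#' @return list of class `ordinal_eval` with `mae`, `mse`, `pacc`, `n`,
#'   `confusion`.
#' @export
ordinal_eval <- function(gold, pred, P = max(gold, pred),
                         ties = c("strict", "half")) {
  pa <- tryCatch(pacc(gold, pred, ties = ties), error = function(e) NA_real_)
  structure(list(mae = mae(gold, pred), mse = mse(gold, pred), pacc = pa,
                 n = length(gold), confusion = confusion(gold, pred, P)),
            class = "ordinal_eval")
}

#' @exportS3Method base::print
print.ordinal_eval <- function(x, ...) {
  cat(sprintf("n = %d   MAE = %.4f   MSE = %.4f   PAcc = %s\n",
              x$n, x$mae, x$mse,
              if (is.na(x$pacc)) "undefined" else sprintf("%.2f%%", 100 * x$pacc)))
  invisible(x)
}

#' @export
as.data.frame.ordinal_eval <- function(x, ...) {
  data.frame(n = x$n, mae = x$mae, mse = x$mse, pacc = x$pacc)
}

#' Per-feature contribution of an ordinal-partitioning model
#'
#' The contribution of feature j is the L2 norm of the j-th row of the
#' stacked weight matrix W (one column per sub-model): features that carry
#' large weight in any partition rank high. The bias row, when present, is
#' excluded.
#'
#' @param model a fitted [svmop()] model (or a bare weight matrix).
#' @return list of class `feature_importance`: `con` (length-l nonnegative
#'   contributions), `ranking` (feature indices sorted by decreasing
#'   contribution, ties broken toward the lower index), `names`.
#' @export
feature_contribution <- function(model) {
  if (inherits(model, "svmop")) {
    W <- model$W
    if (model$bias) W <- W[-nrow(W), , drop = FALSE]
    nms <- model$feature_names
  } else {
    W <- as.matrix(model)
    nms <- rownames(W)
  }
  con <- sqrt(rowSums(W^2))
  ranking <- order(-con, seq_along(con))
  structure(list(con = con, ranking = ranking, names = nms),
            class = "feature_importance")
}

#' Top-k most predictive features
#'
#' @param report a [feature_contribution()] result.
#' @param k how many features (`k <= l`).
#' @param names optional feature names overriding those in the report.
#' @return data.frame with `rank`, `feature` (index), `name`, `con`.
#' @export
top_features <- function(report, k = 10, names = NULL) {
  stopifnot(inherits(report, "feature_importance"), k <= length(report$con))
  idx <- utils::head(report$ranking, k)
  nms <- if (!is.null(names)) names else report$names
  data.frame(rank = seq_len(length(idx)), feature = idx,
             name = if (is.null(nms)) paste0("x", idx) else nms[idx],
             con = report$con[idx], row.names = NULL)
}

#' @exportS3Method base::print
print.feature_importance <- function(x, k = 10, ...) {
  cat("Feature contributions (||W(j,:)||2), top", min(k, length(x$con)), "of",
      length(x$con), "features:\n")
  print(top_features(x, min(k, length(x$con))), row.names = FALSE)
  invisible(x)
}
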