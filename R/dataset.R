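#' Construct an ordinal dataset
#'
#' The universal input container of the package: a sparse design matrix
#' paired with integer labels from an ordered set \{1, ..., P\}. All fitting
#' functions ([svmop()], [svc_ovr()], [svr_rounded()], [lr_ovr()]) accept an
#' `ordinal_dataset` or a bare matrix plus label vector.
#'
#' @param X numeric matrix or `Matrix::sparseMatrix` (n instances x l
#'   features). Stored internally as a `dgCMatrix`.
#' @param y integer labels, each in `1..P`.
#' @param P number of ordered categories; defaults to `max(y)`. Must be at
#'   least 2.
#' @param feature_names optional character vector of length `ncol(X)`.
#' @param label_map optional named integer vector recording a remapping from
#'   original label codes to `1..P` (as produced by [read_svmlight()]).
#'
#' @return An object of class `ordinal_dataset`: a list with elements `X`
#'   (dgCMatrix), `y` (integer), `P`, `feature_names`, `label_map`.
#' @examples
#' ds <- ordinal_dataset(matrix(rnorm(20), 5), y = c(1, 2, 3, 2, 1), P = 3)
#' dim(ds)
#' @export
ordinal_dataset <- function(X, y, P = max(y), feature_names = NULL,
                            label_map = NULL) {
  X <- as_dgc(X)
  y <- as.integer(y)
  if (nrow(X) != length(y))
    stop("nrow(X) [", nrow(X), "] != length(y) [", length(y), "]")
  if (length(y) > 0 && (any(y < 1L) || any(y > P)))
    stop("labels must be integers in [1, P]")
  P <- as.integer(P)
  if (P < 2L) stop("P must be >= 2")
  if (!is.null(feature_names) && length(feature_names) != ncol(X))
    stop("feature_names length must equal ncol(X)")
  structure(list(X = X, y = y, P = P, feature_names = feature_names,
                 label_map = label_map),
            class = "ordinal_dataset")
}

#' @export
dim.ordinal_dataset <- function(x) dim(x$X)

#' @exportS3Method base::print
print.ordinal_dataset <- function(x, ...) {
  cat("Ordinal dataset: ", nrow(x$X), " instances, ", ncol(x$X),
      " features, P = ", x$P, " ordered categories\n", sep = "")
  tab <- tabulate(x$y, nbins = x$P)
  cat("Class counts:", paste(tab, collapse = " "), "\n")
  invisible(x)
}

# Coerce dense or sparse input to a dgCMatrix.
as_dgc <- function(X) {
  if (methods::is(X, "dgCMatrix")) return(X)
  if (is.matrix(X)) {
    storage.mode(X) <- "double"
    X <- Matrix::Matrix(X, sparse = TRUE)
  }
  methods::as(methods::as(methods::as(X, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

# Append a constant-1 bias column. A one-column sparse matrix (never a
# bare vector) keeps cbind2 well-defined for zero-row inputs and keeps
# the result in compressed sparse form.
add_bias_col <- function(X) {
  n <- nrow(X)
  ones <- Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                               dims = c(n, 1L))
  methods::as(methods::cbind2(X, ones), "CsparseMatrix")
}

# Remap arbitrary integer label codes onto consecutive 1..P, preserving order.
remap_labels <- function(raw) {
  lev <- sort(unique(raw))
  map <- stats::setNames(seq_along(lev), lev)
  list(y = map[as.character(raw)], map = map)
}

#' Read a dataset in SVMlight/LIBSVM sparse format
#'
#' Lines have the form `<label> <index>:<value> ...` with 1-based, strictly
#' increasing feature indices. Labels need not be consecutive: they are
#' remapped onto `1..P` preserving order, and the mapping is stored in the
#' returned dataset's `label_map`.
#'
#' @param path file path.
#' @param n_features optional feature count; defaults to the largest index
#'   seen. Useful when a test file must align with a training matrix.
#' @return An [ordinal_dataset()] with a `label_map` attribute.
#' @seealso [write_svmlight()]
#' @export
read_svmlight <- function(path, n_features = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no instances in ", path)
  labs <- numeric(length(lines))
  ii <- jj <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[ln]]), "[[:space:]]+")[[1]]
    lab <- suppressWarnings(as.numeric(toks[1]))
    if (is.na(lab))
      stop("line ", ln, ": non-numeric label '", toks[1], "'")
    labs[ln] <- lab
    if (length(toks) > 1L) {
      kv <- strsplit(toks[-1], ":", fixed = TRUE)
      bad <- lengths(kv) != 2L
      if (any(bad))
        stop("line ", ln, ": malformed feature token '",
             toks[-1][which(bad)[1]], "'")
      idx <- suppressWarnings(as.integer(vapply(kv, `[`, "", 1L)))
      val <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
      if (anyNA(idx) || anyNA(val))
        stop("line ", ln, ": non-numeric feature token")
      if (any(idx < 1L))
        stop("line ", ln, ": feature indices must be >= 1")
      if (is.unsorted(idx, strictly = TRUE))
        stop("line ", ln, ": feature indices must be strictly increasing")
      ii[[ln]] <- idx
      jj[[ln]] <- val
    } else {
      ii[[ln]] <- integer(0)
      jj[[ln]] <- numeric(0)
    }
  }
  l <- max(c(unlist(ii), 0L))
  if (!is.null(n_features)) {
    if (n_features < l) stop("n_features smaller than max stored index")
    l <- as.integer(n_features)
  }
  rows <- rep.int(seq_along(lines), lengths(ii))
  X <- Matrix::sparseMatrix(i = rows, j = unlist(ii), x = unlist(jj),
                            dims = c(length(lines), l))
  rm <- remap_labels(labs)
  ordinal_dataset(X, rm$y, P = max(rm$y), label_map = rm$map)
}

#' Write a dataset in SVMlight/LIBSVM sparse format
#'
#' Values are printed with 17 significant digits so that
#' `read_svmlight(write_svmlight(ds))` reproduces `X` and `y` exactly.
#'
#' @param ds an [ordinal_dataset()].
#' @param path output file path.
#' @export
write_svmlight <- function(ds, path) {
  stopifnot(inherits(ds, "ordinal_dataset"))
  Xt <- Matrix::t(ds$X)  # CSC of t(X): nonzeros of row i are contiguous
  p <- Xt@p; i <- Xt@i; v <- Xt@x
  lines <- character(nrow(ds$X))
  for (r in seq_len(nrow(ds$X))) {
    k <- if (p[r + 1] > p[r]) (p[r] + 1L):p[r + 1] else integer(0)
    feats <- if (length(k))
      paste0(i[k] + 1L, ":", sprintf("%.17g", v[k]), collapse = " ")
    else ""
    lines[r] <- trimws(paste(ds$y[r], feats))
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a dense CSV dataset
#'
#' Expects a header row; the label column is named `label` (or given by
#' `label_col`), all other columns are numeric features.
#'
#' @param path file path.
#' @param label_col name of the label column.
#' @return An [ordinal_dataset()].
#' @export
read_ordinal_csv <- function(path, label_col = "label") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_col %in% names(df))
    stop("no column named '", label_col, "' in ", path)
  y_raw <- df[[label_col]]
  Xd <- as.matrix(df[setdiff(names(df), label_col)])
  storage.mode(Xd) <- "double"
  rm <- remap_labels(y_raw)
  ordinal_dataset(Xd, rm$y, P = max(rm$y),
                  feature_names = colnames(Xd), label_map = rm$map)
}

#' k-fold cross-validation split
#'
#' Randomly partitions instances into k folds, reproducibly from `seed`.
#' With `stratified = TRUE` each class is dealt round-robin across folds so
#' per-class fold counts differ by at most one.
#'
#' @param ds an [ordinal_dataset()] (or an integer label vector).
#' @param k number of folds (>= 2).
#' @param stratified balance class counts across folds.
#' @param seed integer seed.
#' @return Object of class `fold_assignment`: list with `fold_id` (integer
#'   in `1..k` per instance), `k`, `seed`.
#' @export
kfold_split <- function(ds, k = 5L, stratified = TRUE, seed = 1L) {
  y <- if (inherits(ds, "ordinal_dataset")) ds$y else as.integer(ds)
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k [", k, "] exceeds number of instances [", n, "]")
  fold <- integer(n)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    if (stratified) {
      # deal classes consecutively round-robin so every fold is non-empty
      # whenever n >= k, while per-class counts differ by at most one
      pos <- 0L
      for (cls in sort(unique(y))) {
        id <- which(y == cls)
        id <- id[sample.int(length(id))]
        fold[id] <- 1L + (pos + seq_along(id) - 1L) %% k
        pos <- (pos + length(id)) %% k
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  structure(list(fold_id = fold, k = k, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @exportS3Method base::print
print.fold_assignment <- function(x, ...) {
  cat("k =", x$k, "folds over", length(x$fold_id),
      "instances (seed", paste0(x$seed, ")"), "\n")
  print(table(fold = x$fold_id))
  invisible(x)
}
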