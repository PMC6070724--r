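MODEL_FORMAT_VERSION <- "1.0"

#' Save a fitted model as portable JSON
#'
#' Supports [svmop()], [svc_ovr()] / [lr_ovr()], [svr_rounded()] and
#' [gbdt()] fits. Numbers are written at full precision so
#' `read_model(write_model(m))` round-trips exactly.
#'
#' @param model a fitted model object.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  payload <- if (inherits(model, "svmop")) {
    list(family = "svmop", P = model$P, C = model$C, bias = model$bias,
         prediction = model$prediction, W = model$W,
         feature_names = model$feature_names, warnings = model$warnings)
  } else if (inherits(model, "ovr_model")) {
    list(family = model$family, P = model$P, C = model$C, bias = model$bias,
         W = model$W, feature_names = model$feature_names)
  } else if (inherits(model, "svr_model")) {
    list(family = "svr", P = model$P, C = model$C, bias = model$bias,
         eps = model$eps, w = model$w, feature_names = model$feature_names)
  } else if (inherits(model, "gbdt")) {
    list(family = "gbdt", init = model$init,
         learning_rate = model$learning_rate, rounds = model$rounds,
         depth = model$depth, d = model$d, n_leaves = model$n_leaves,
         train_loss = model$train_loss, trees = model$trees)
  } else stop("unsupported model class: ", paste(class(model), collapse = "/"))
  payload$format_version <- MODEL_FORMAT_VERSION
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(NULL)
}

#' @rdname write_model
#' @return the reconstructed model object.
#' @export
read_model <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  fam <- o$family
  nm <- function(x) if (is.null(x) || length(x) == 0) NULL else x
  if (fam == "svmop") {
    structure(list(W = as.matrix(o$W), P = as.integer(o$P), C = o$C,
                   bias = isTRUE(o$bias), prediction = o$prediction,
                   feature_names = nm(o$feature_names),
                   states = NULL, warnings = o$warnings %||% character(0),
                   control = NULL, call = NULL),
              class = "svmop")
  } else if (fam %in% c("svc", "lr")) {
    structure(list(W = as.matrix(o$W), P = as.integer(o$P), C = o$C,
                   bias = isTRUE(o$bias), family = fam,
                   feature_names = nm(o$feature_names),
                   states = NULL, call = NULL),
              class = "ovr_model")
  } else if (fam == "svr") {
    structure(list(w = as.numeric(o$w), P = as.integer(o$P), C = o$C,
                   bias = isTRUE(o$bias), eps = o$eps, family = "svr",
                   feature_names = nm(o$feature_names), call = NULL),
              class = "svr_model")
  } else if (fam == "gbdt") {
    trees <- lapply(o$trees, function(tr) {
      tr <- as.data.frame(tr)
      tr$feature <- as.integer(tr$feature)
      tr$left <- as.integer(tr$left); tr$right <- as.integer(tr$right)
      tr$leaf_id <- as.integer(tr$leaf_id)
      tr
    })
    structure(list(init = o$init, trees = trees,
                   n_leaves = as.integer(o$n_leaves),
                   learning_rate = o$learning_rate,
                   rounds = as.integer(o$rounds), depth = as.integer(o$depth),
                   train_loss = as.numeric(o$train_loss), d = as.integer(o$d),
                   call = NULL),
              class = "gbdt")
  } else stop("unknown model family in ", path, ": ", fam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
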