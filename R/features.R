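#' Construct a consultation record
#'
#' A structured doctor/patient message thread: each side is a sequence of
#' timestamped turns, optionally with a satisfaction label in `1..5`.
#'
#' @param patient,doctor data.frames with columns `t` (numeric timestamp,
#'   seconds) and `text` (character), timestamps non-decreasing.
#' @param label optional integer satisfaction rating.
#' @return list of class `consultation_record`.
#' @export
consultation_record <- function(patient, doctor, label = NULL) {
  as_turns <- function(d) {
    if (is.null(d) || NROW(d) == 0L)
      return(data.frame(t = numeric(0), text = character(0)))
    d <- as.data.frame(d)[c("t", "text")]
    d$t <- as.numeric(d$t); d$text <- as.character(d$text)
    if (is.unsorted(d$t)) stop("timestamps must be non-decreasing")
    d
  }
  structure(list(patient = as_turns(patient), doctor = as_turns(doctor),
                 label = if (is.null(label)) NA_integer_ else as.integer(label)),
            class = "consultation_record")
}

#' @exportS3Method base::print
print.consultation_record <- function(x, ...) {
  cat("Consultation:", nrow(x$patient), "patient turn(s),",
      nrow(x$doctor), "doctor turn(s), label =",
      if (is.na(x$label)) "unlabeled" else x$label, "\n")
  invisible(x)
}

#' Bundle the three medical term dictionaries
#'
#' @param symptoms,illnesses,medicines character vectors of terms (need not
#'   be disjoint; real dictionaries overlap).
#' @return list of class `medical_dictionaries`.
#' @export
medical_dictionaries <- function(symptoms, illnesses, medicines) {
  chk <- function(x, nm) {
    x <- unique(as.character(x))
    if (any(!nzchar(x))) stop(nm, ": empty terms not allowed")
    x
  }
  structure(list(symptoms = chk(symptoms, "symptoms"),
                 illnesses = chk(illnesses, "illnesses"),
                 medicines = chk(medicines, "medicines")),
            class = "medical_dictionaries")
}

#' Read term dictionaries from one-term-per-line text files
#'
#' @param symptoms_path,illnesses_path,medicines_path UTF-8 text files.
#' @return a [medical_dictionaries()] object.
#' @export
read_dictionaries <- function(symptoms_path, illnesses_path, medicines_path) {
  rd <- function(p) {
    x <- readLines(p, encoding = "UTF-8")
    x[nzchar(trimws(x))]
  }
  medical_dictionaries(rd(symptoms_path), rd(illnesses_path),
                       rd(medicines_path))
}

#' @rdname read_dictionaries
#' @param dicts a [medical_dictionaries()] object.
#' @export
write_dictionaries <- function(dicts, symptoms_path, illnesses_path,
                               medicines_path) {
  writeLines(dicts$symptoms, symptoms_path, useBytes = TRUE)
  writeLines(dicts$illnesses, illnesses_path, useBytes = TRUE)
  writeLines(dicts$medicines, medicines_path, useBytes = TRUE)
  invisible(NULL)
}

# Count dictionary-term occurrences in text under the longest-match,
# non-overlapping convention: scan left to right, at each position take the
# longest term starting there (if any), consume it, and continue after it.
count_dict_terms <- function(text, terms) {
  if (!nzchar(text) || length(terms) == 0L) return(0L)
  lens <- sort(unique(nchar(terms)), decreasing = TRUE)
  sets <- lapply(lens, function(L) {
    e <- new.env(parent = emptyenv(), size = 64L)
    for (tm in terms[nchar(terms) == L]) assign(tm, TRUE, envir = e)
    e
  })
  n <- nchar(text)
  count <- 0L
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (s in seq_along(lens)) {
      L <- lens[s]
      if (i + L - 1L > n) next
      if (!is.null(sets[[s]][[substr(text, i, i + L - 1L)]])) { hit <- L; break }
    }
    if (hit > 0L) { count <- count + 1L; i <- i + hit } else i <- i + 1L
  }
  count
}

#' Extract the eight customized consultation features
#'
#' F1/F2/F3: occurrence counts of symptom / illness / medicine dictionary
#' terms in the concatenated doctor text (longest-match, non-overlapping);
#' F4: number of patient turns; F5: number of doctor turns; F6: response
#' time to the patient's first question in seconds (`NA` when the doctor
#' never replied — imputed with the training maximum at matrix-assembly
#' time); F7/F8: character counts of the patient / doctor text.
#'
#' @param rec a [consultation_record()].
#' @param dicts a [medical_dictionaries()].
#' @return named numeric vector of length 8 (`F1`..`F8`).
#' @export
extract_customized <- function(rec, dicts) {
  stopifnot(inherits(rec, "consultation_record"),
            inherits(dicts, "medical_dictionaries"))
  if (nrow(rec$patient) == 0L) stop("empty consultation: no patient turns")
  doc_text <- paste(rec$doctor$text, collapse = " ")
  pat_text <- paste(rec$patient$text, collapse = " ")
  f6 <- if (nrow(rec$doctor) == 0L) NA_real_
        else rec$doctor$t[1] - rec$patient$t[1]
  c(F1 = count_dict_terms(doc_text, dicts$symptoms),
    F2 = count_dict_terms(doc_text, dicts$illnesses),
    F3 = count_dict_terms(doc_text, dicts$medicines),
    F4 = nrow(rec$patient),
    F5 = nrow(rec$doctor),
    F6 = f6,
    F7 = nchar(gsub("[[:space:]]", "", pat_text)),
    F8 = nchar(gsub("[[:space:]]", "", doc_text)))
}

#' Whitespace tokenizer
#'
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
tokenize_whitespace <- function(text) {
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Greedy dictionary segmenter for unsegmented text
#'
#' Longest-match segmentation against a term list: at each position emit
#' the longest dictionary term starting there, falling back to a single
#' character. A crude stand-in for a real word segmenter, sufficient for
#' delimiter-free scripts when a domain dictionary is available.
#'
#' @param text character scalar.
#' @param terms character vector of dictionary terms.
#' @return character vector of tokens.
#' @export
tokenize_dictionary <- function(text, terms) {
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) return(character(0))
  lens <- sort(unique(nchar(terms)), decreasing = TRUE)
  sets <- lapply(lens, function(L) {
    e <- new.env(parent = emptyenv(), size = 64L)
    for (tm in terms[nchar(terms) == L]) assign(tm, TRUE, envir = e)
    e
  })
  n <- nchar(text)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (s in seq_along(lens)) {
      L <- lens[s]
      if (i + L - 1L > n) next
      if (!is.null(sets[[s]][[substr(text, i, i + L - 1L)]])) { hit <- L; break }
    }
    if (hit == 0L) hit <- 1L
    out <- c(out, substr(text, i, i + hit - 1L))
    i <- i + hit
  }
  out
}

#' Build a unigram + bigram vocabulary
#'
#' Unigrams and contiguous bigrams (joined with `_`) whose document
#' frequency reaches `min_df`, in deterministic lexicographic column order.
#'
#' @param corpus list of token vectors (one per document).
#' @param min_df minimum document frequency (>= 1).
#' @param ngrams integer vector of n-gram orders, subset of `1:2`.
#' @return list of class `text_vocabulary`: `terms`, `df`, `index`
#'   (named term -> column map), `n_docs`.
#' @export
build_vocabulary <- function(corpus, min_df = 1L, ngrams = 1:2) {
  if (length(corpus) == 0L) stop("empty corpus")
  stopifnot(min_df >= 1L, all(ngrams %in% 1:2))
  doc_terms <- lapply(corpus, doc_ngrams, ngrams = ngrams)
  df_tab <- table(unlist(lapply(doc_terms, unique)))
  keep <- sort(names(df_tab)[df_tab >= min_df])
  structure(list(terms = keep,
                 df = as.integer(df_tab[keep]),
                 index = stats::setNames(seq_along(keep), keep),
                 n_docs = length(corpus),
                 ngrams = as.integer(ngrams)),
            class = "text_vocabulary")
}

doc_ngrams <- function(toks, ngrams) {
  out <- character(0)
  if (1L %in% ngrams) out <- c(out, toks)
  if (2L %in% ngrams && length(toks) >= 2L)
    out <- c(out, paste(toks[-length(toks)], toks[-1], sep = "_"))
  out
}

#' @exportS3Method base::print
print.text_vocabulary <- function(x, ...) {
  cat("Vocabulary:", length(x$terms), "terms over", x$n_docs, "documents\n")
  invisible(x)
}

#' Persist / load a vocabulary as TSV (term, column, df)
#'
#' @param vocab a [build_vocabulary()] result.
#' @param path TSV file path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(
    data.frame(term = vocab$terms, column = seq_along(vocab$terms),
               df = vocab$df, n_docs = vocab$n_docs,
               ngrams = paste(vocab$ngrams, collapse = ",")),
    path, sep = "\t", row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  df <- df[order(df$column), ]
  structure(list(terms = df$term, df = as.integer(df$df),
                 index = stats::setNames(seq_along(df$term), df$term),
                 n_docs = df$n_docs[1],
                 ngrams = as.integer(strsplit(as.character(df$ngrams[1]),
                                              ",")[[1]])),
            class = "text_vocabulary")
}

#' TF-IDF transform of a tokenized corpus
#'
#' Value = raw in-document term count times the smoothed inverse document
#' frequency `ln((1 + N) / (1 + df)) + 1` from the fitting corpus; rows are
#' then L2-normalized (zero rows stay zero). Terms outside the vocabulary
#' are dropped, so the transform applies unchanged to unseen documents.
#'
#' @param corpus list of token vectors.
#' @param vocab a [build_vocabulary()] result.
#' @return sparse `dgCMatrix`, `length(corpus)` x `length(vocab$terms)`.
#' @export
tfidf_transform <- function(corpus, vocab) {
  stopifnot(inherits(vocab, "text_vocabulary"))
  ii <- jj <- vv <- vector("list", length(corpus))
  idf <- log((1 + vocab$n_docs) / (1 + vocab$df)) + 1
  for (d in seq_along(corpus)) {
    terms <- doc_ngrams(corpus[[d]], vocab$ngrams)
    cols <- vocab$index[terms]
    cols <- cols[!is.na(cols)]
    if (length(cols)) {
      tf <- table(cols)
      jj[[d]] <- as.integer(names(tf))
      ii[[d]] <- rep.int(d, length(tf))
      vv[[d]] <- as.numeric(tf) * idf[as.integer(names(tf))]
    }
  }
  M <- Matrix::sparseMatrix(i = c(unlist(ii), integer(0)),
                            j = c(unlist(jj), integer(0)),
                            x = c(unlist(vv), numeric(0)),
                            dims = c(length(corpus), length(vocab$terms)))
  rn <- sqrt(Matrix::rowSums(M^2))
  rn[rn == 0] <- 1
  Matrix::Diagonal(x = 1 / rn) %*% M
}

# full consultation text (all turns, both sides) as one token stream
record_tokens <- function(rec, tokenizer) {
  tokenizer(paste(c(rec$patient$text, rec$doctor$text), collapse = " "))
}

# raw customized feature matrix (n x 8) with F6 possibly NA
customized_matrix <- function(records, dicts) {
  t(vapply(records, extract_customized, numeric(8), dicts = dicts))
}

#' Fit a consultation featurizer
#'
#' Learns everything needed to map consultation records to a design
#' matrix: the text vocabulary and IDF weights, the training statistics
#' that z-score the customized block (and the F6 missing-reply sentinel,
#' the training maximum), and — for the boosted feature set — a gradient-
#' boosted tree ensemble over the 8 customized features whose leaf
#' memberships become one-hot columns.
#'
#' Feature sets: `"T"` text only; `"T+C"` text + customized; `"T+C+B"`
#' text + customized + boosted leaf encodings.
#'
#' @param records list of labeled [consultation_record()]s.
#' @param dicts a [medical_dictionaries()].
#' @param feature_set one of `"T"`, `"T+C"`, `"T+C+B"`.
#' @param tokenizer function mapping text to a token vector.
#' @param min_df vocabulary document-frequency cutoff.
#' @param gbdt_rounds,gbdt_depth,gbdt_lr GBDT hyperparameters for the
#'   boosted block.
#' @return object of class `featurizer`; use [design_matrix()] to apply it.
#' @export
fit_featurizer <- function(records, dicts,
                           feature_set = c("T+C+B", "T", "T+C"),
                           tokenizer = tokenize_whitespace, min_df = 2L,
                           gbdt_rounds = 30L, gbdt_depth = 3L,
                           gbdt_lr = 0.1) {
  feature_set <- match.arg(feature_set)
  corpus <- lapply(records, record_tokens, tokenizer = tokenizer)
  vocab <- build_vocabulary(corpus, min_df = min_df)
  fz <- list(feature_set = feature_set, vocab = vocab,
             tokenizer = tokenizer, dicts = dicts)
  if (feature_set != "T") {
    Craw <- customized_matrix(records, dicts)
    f6max <- suppressWarnings(max(Craw[, "F6"], na.rm = TRUE))
    if (!is.finite(f6max)) f6max <- 0
    Craw[is.na(Craw[, "F6"]), "F6"] <- f6max
    ctr <- colMeans(Craw)
    sds <- apply(Craw, 2, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    fz$f6_sentinel <- f6max
    fz$center <- ctr
    fz$scale <- sds
    if (feature_set == "T+C+B") {
      y <- vapply(records, function(r) r$label, integer(1))
      if (anyNA(y)) stop("boosted feature set requires labeled records")
      fz$gbdt <- gbdt(Craw, as.numeric(y), rounds = gbdt_rounds,
                      depth = gbdt_depth, learning_rate = gbdt_lr)
    }
  }
  class(fz) <- "featurizer"
  fz
}

#' @exportS3Method base::print
print.featurizer <- function(x, ...) {
  cat("Consultation featurizer, feature set", x$feature_set, "\n")
  cat("  text block:", length(x$vocab$terms), "TF-IDF columns\n")
  if (x$feature_set != "T") cat("  customized block: 8 z-scored columns\n")
  if (!is.null(x$gbdt))
    cat("  boosted block:", sum(x$gbdt$n_leaves), "leaf one-hot columns\n")
  invisible(x)
}

#' Assemble the design matrix for a set of consultation records
#'
#' Applies a fitted [fit_featurizer()] to records, producing column blocks
#' in the order text | customized | leaf one-hot, with the customized
#' block z-scored by the training statistics.
#'
#' @param featurizer a fitted [fit_featurizer()].
#' @param records list of [consultation_record()]s.
#' @param P number of ordered categories when labels are present.
#' @return an [ordinal_dataset()] when every record is labeled, otherwise
#'   a bare sparse matrix with a `feature_names` attribute.
#' @export
design_matrix <- function(featurizer, records, P = 5L) {
  stopifnot(inherits(featurizer, "featurizer"))
  corpus <- lapply(records, record_tokens, tokenizer = featurizer$tokenizer)
  blocks <- list(tfidf_transform(corpus, featurizer$vocab))
  nms <- paste0("tfidf:", featurizer$vocab$terms)
  if (featurizer$feature_set != "T") {
    Craw <- customized_matrix(records, featurizer$dicts)
    Craw[is.na(Craw[, "F6"]), "F6"] <- featurizer$f6_sentinel
    Cz <- sweep(sweep(Craw, 2, featurizer$center), 2, featurizer$scale, "/")
    blocks <- c(blocks, list(methods::as(Cz, "CsparseMatrix")))
    nms <- c(nms, colnames(Craw))
    if (featurizer$feature_set == "T+C+B") {
      onehot <- predict(featurizer$gbdt, Craw, type = "onehot")
      blocks <- c(blocks, list(onehot))
      nms <- c(nms, colnames(onehot))
    }
  }
  X <- do.call(cbind, blocks)
  y <- vapply(records, function(r) r$label, integer(1))
  if (anyNA(y)) {
    attr(X, "feature_names") <- nms
    return(X)
  }
  ordinal_dataset(X, y, P = P, feature_names = nms)
}

#' Read / write consultation records as JSON lines
#'
#' One record per line: `{"label": 4, "patient": [{"t": 0, "text": "..."}],
#' "doctor": [...]}` with `label` null for unlabeled records.
#'
#' @param path file path.
#' @return list of [consultation_record()]s.
#' @export
read_consultations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    consultation_record(o$patient, o$doctor,
                        label = if (is.null(o$label)) NULL else o$label)
  })
}

#' @rdname read_consultations
#' @param records list of [consultation_record()]s.
#' @export
write_consultations <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(
      label = if (is.na(r$label)) NULL else r$label,
      patient = r$patient, doctor = r$doctor),
      auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}
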