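mk_rec <- function(patient_texts, doctor_texts, p_t = NULL, d_t = NULL,
                   label = 3L) {
  if (is.null(p_t)) p_t <- seq_along(patient_texts) - 1
  if (is.null(d_t)) d_t <- seq_along(doctor_texts) + 9
  consultation_record(
    patient = data.frame(t = p_t, text = patient_texts),
    doctor = if (length(doctor_texts))
      data.frame(t = d_t, text = doctor_texts) else NULL,
    label = label)
}

toy_dicts <- medical_dictionaries(symptoms = c("cough", "fever"),
                                  illnesses = c("smallpox", "flu"),
                                  medicines = c("aspirin"))

test_that("customized features count turns, characters and dictionary hits", {
  rec <- mk_rec(c("i have a cough", "and fever"),
                c("sounds like flu", "take aspirin twice", "aspirin helps"),
                p_t = c(0, 30), d_t = c(120, 200, 260))
  f <- extract_customized(rec, toy_dicts)
  expect_equal(unname(f["F1"]), 0)       # no symptom terms in doctor text
  expect_equal(unname(f["F2"]), 1)       # "flu"
  expect_equal(unname(f["F3"]), 2)       # "aspirin" twice (occurrences)
  expect_equal(unname(f["F4"]), 2)
  expect_equal(unname(f["F5"]), 3)
  expect_equal(unname(f["F6"]), 120)     # first reply at 120, question at 0
  expect_equal(unname(f["F7"]),
               nchar(gsub(" ", "", "i have a cough and fever")))
})

test_that("missing doctor reply yields NA response time; no patient turns errors", {
  rec <- mk_rec("hello doctor", character(0))
  f <- extract_customized(rec, toy_dicts)
  expect_true(is.na(f["F6"]))
  expect_equal(unname(f["F5"]), 0)
  rec2 <- consultation_record(NULL, data.frame(t = 1, text = "hi"))
  expect_error(extract_customized(rec2, toy_dicts), "empty consultation")
})

test_that("dictionary counting is longest-match and non-overlapping", {
  d <- medical_dictionaries(symptoms = "x", illnesses = c("AB", "ABC"),
                            medicines = "x")
  rec <- mk_rec("q", "ABC")
  f <- extract_customized(rec, d)
  expect_equal(unname(f["F2"]), 1)  # "ABC" consumes the span, "AB" unmatched
})

test_that("dictionary counts equal the exhaustive span oracle", {
  set.seed(66)
  alphabet <- c("a", "b", "c")
  for (trial in 1:20) {
    text <- paste(sample(alphabet, 30, replace = TRUE), collapse = "")
    terms <- unique(replicate(5, paste(
      sample(alphabet, sample(1:3, 1), replace = TRUE), collapse = "")))
    expect_equal(svmop:::count_dict_terms(text, terms),
                 dict_count_oracle(text, terms),
                 info = paste("text:", text))
  }
})

test_that("vocabulary keeps n-grams by document frequency in sorted order", {
  corpus <- list(c("a", "b"), c("b", "c"))
  v1 <- build_vocabulary(corpus, min_df = 1)
  expect_identical(v1$terms, sort(c("a", "b", "c", "a_b", "b_c")))
  v2 <- build_vocabulary(corpus, min_df = 2)
  expect_identical(v2$terms, "b")
  # deterministic across repeated builds
  expect_identical(build_vocabulary(corpus, 1)$index, v1$index)
  expect_error(build_vocabulary(list(), 1), "empty corpus")
})

test_that("tf-idf matches a hand-computed oracle and is L2-normalized", {
  corpus <- list(c("a", "b", "a"), c("b", "c"), c("c", "c", "d"))
  vocab <- build_vocabulary(corpus, min_df = 1)
  M <- as.matrix(tfidf_transform(corpus, vocab))
  O <- tfidf_oracle(corpus, vocab$terms, vocab$df, vocab$n_docs)
  expect_equal(M, O, ignore_attr = TRUE)
  rn <- sqrt(rowSums(M^2))
  expect_equal(rn, rep(1, 3), ignore_attr = TRUE)
  # a term present in every document has idf exactly 1 pre-normalization
  expect_equal(log((1 + 3) / (1 + 3)) + 1, 1)
  # unknown terms are dropped; an all-unknown document gives a zero row
  M2 <- as.matrix(tfidf_transform(list(c("zz", "qq")), vocab))
  expect_equal(sum(M2), 0)
})

test_that("transforming the fitting corpus reproduces fit-time values", {
  corp <- gen_consultations(corpus_spec(n = 40, seed = 31))
  fz <- fit_featurizer(corp$records, corp$dicts, feature_set = "T")
  d1 <- design_matrix(fz, corp$records)
  d2 <- design_matrix(fz, corp$records)
  expect_equal(as.matrix(d1$X), as.matrix(d2$X), tolerance = 0)
})

test_that("design matrix widths follow the feature-set contract", {
  corp <- gen_consultations(corpus_spec(n = 50, seed = 23))
  fz_t <- fit_featurizer(corp$records, corp$dicts, feature_set = "T")
  fz_tc <- fit_featurizer(corp$records, corp$dicts, feature_set = "T+C")
  fz_tcb <- fit_featurizer(corp$records, corp$dicts, feature_set = "T+C+B",
                           gbdt_rounds = 8)
  V <- length(fz_t$vocab$terms)
  expect_equal(ncol(design_matrix(fz_t, corp$records)$X), V)
  expect_equal(ncol(design_matrix(fz_tc, corp$records)$X), V + 8)
  expect_equal(ncol(design_matrix(fz_tcb, corp$records)$X),
               V + 8 + sum(fz_tcb$gbdt$n_leaves))
  nm <- design_matrix(fz_tcb, corp$records)$feature_names
  expect_equal(sum(startsWith(nm, "tfidf:")), V)
  expect_equal(sum(nm %in% paste0("F", 1:8)), 8)
  expect_equal(sum(startsWith(nm, "gbdt_")), sum(fz_tcb$gbdt$n_leaves))
})

test_that("consultation records round-trip through JSON lines", {
  corp <- gen_consultations(corpus_spec(n = 15, seed = 12))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_consultations(corp$records, path)
  back <- read_consultations(path)
  expect_length(back, 15)
  for (i in seq_len(15)) {
    expect_equal(back[[i]]$patient, corp$records[[i]]$patient)
    expect_equal(back[[i]]$doctor, corp$records[[i]]$doctor)
    expect_identical(back[[i]]$label, corp$records[[i]]$label)
  }
})

test_that("vocabulary and dictionaries persist through their text formats", {
  corpus <- list(c("a", "b", "a"), c("b", "c"))
  vocab <- build_vocabulary(corpus, min_df = 1)
  vp <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(vocab, vp)
  vb <- read_vocabulary(vp)
  expect_identical(vb$terms, vocab$terms)
  expect_identical(vb$df, vocab$df)
  expect_equal(vb$n_docs, vocab$n_docs)

  paths <- replicate(3, withr::local_tempfile(fileext = ".txt"))
  write_dictionaries(toy_dicts, paths[1], paths[2], paths[3])
  db <- read_dictionaries(paths[1], paths[2], paths[3])
  expect_identical(db$illnesses, toy_dicts$illnesses)
})

test_that("the greedy dictionary segmenter prefers long terms", {
  toks <- tokenize_dictionary("ABCab", c("AB", "ABC"))
  expect_identical(toks, c("ABC", "a", "b"))
  expect_identical(tokenize_whitespace("  a  b "), c("a", "b"))
  expect_identical(tokenize_dictionary("", "AB"), character(0))
})
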