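test_that("label binarization answers 'is the rank greater than p'", {
  expect_equal(binarize_labels(3, 2), 1)
  expect_equal(binarize_labels(2, 2), -1)
  expect_equal(binarize_labels(1:5, 4), c(-1, -1, -1, -1, 1))
})

test_that("counting rule covers the edge cases and all sign patterns", {
  # no positive score -> rank 1; all positive -> rank P
  expect_equal(rank_from_scores(c(-0.2, -1, -3, -0.5)), 1L)
  expect_equal(rank_from_scores(c(0.5, 0.2, 0.1, 0.3)), 5L)
  # non-monotone pattern under the count rule
  expect_equal(rank_from_scores(c(0.5, -0.1, 0.2, -0.3)), 3L)
  # ties at exactly zero are "not greater than 0"
  expect_equal(rank_from_scores(c(0, 0, 0, 0)), 1L)

  # exhaustive over all 2^4 sign patterns (P = 5): rank = 1 + #positive,
  # and flipping any one score from <=0 to >0 raises the rank by exactly 1
  for (bits in 0:15) {
    pat <- as.integer(intToBits(bits)[1:4])
    s <- ifelse(pat == 1, 0.7, -0.7)
    expect_equal(rank_from_scores(s), 1L + sum(pat))
    for (j in which(pat == 0)) {
      s2 <- s; s2[j] <- 0.7
      expect_equal(rank_from_scores(s2), rank_from_scores(s) + 1L)
    }
  }
})

test_that("sequential rule stops at the first non-positive score", {
  expect_equal(rank_from_scores(c(0.5, -0.1, 0.2, -0.3),
                                rule = "sequential"), 2L)
  expect_equal(rank_from_scores(c(-1, 1, 1, 1), rule = "sequential"), 1L)
  expect_equal(rank_from_scores(c(1, 1, 1, 1), rule = "sequential"), 5L)
  # the two rules agree whenever the score sequence is sign-monotone
  expect_equal(rank_from_scores(c(1, 1, -1, -1), rule = "sequential"),
               rank_from_scores(c(1, 1, -1, -1)))
})

test_that("decision scores are exact inner products", {
  model <- structure(list(W = diag(4)[, 1:4], P = 5L, C = 1, bias = FALSE,
                          prediction = "count", feature_names = NULL),
                     class = "svmop")
  expect_equal(as.numeric(decision_scores(model, c(1, 1, 0, 0))),
               c(1, 1, 0, 0))
  expect_equal(as.numeric(decision_scores(model, rep(0, 4))), rep(0, 4))
  set.seed(1)
  W <- matrix(rnorm(24), 6)
  model$W <- W
  x <- rnorm(6)
  expect_equal(as.numeric(decision_scores(model, x)),
               as.numeric(crossprod(W, x)))
  expect_error(decision_scores(model, rep(0, 5)), "dimension mismatch")
})

test_that("fit on noise-free latent-threshold data reaches training MAE 0", {
  ds <- gen_ordinal(latent_threshold_spec(n = 200, l = 8, P = 4,
                                          noise_sd = 0, seed = 21))
  fit <- svmop(ds, C = 100, control = dcd_control(tol = 1e-5,
                                                  max_epochs = 20000))
  expect_equal(mae(ds$y, predict(fit, ds)), 0)
})

test_that("training is deterministic under a fixed solver seed", {
  ds <- gen_ordinal(latent_threshold_spec(n = 120, l = 6, P = 4,
                                          noise_sd = 0.5, seed = 3))
  f1 <- svmop(ds, C = 1, control = dcd_control(seed = 5))
  f2 <- svmop(ds, C = 1, control = dcd_control(seed = 5))
  expect_identical(f1$W, f2$W)
})

test_that("P = 2 reduces to a single sign-thresholded sub-model", {
  ds <- gen_ordinal(latent_threshold_spec(n = 100, l = 5, P = 2,
                                          noise_sd = 0.3, seed = 8))
  fit <- svmop(ds, C = 1)
  expect_equal(ncol(fit$W), 1L)
  s <- decision_scores(fit, ds)
  expect_identical(as.integer(1L + (s[, 1] > 0)), predict(fit, ds))
})

test_that("batch prediction equals the per-row loop", {
  ds <- gen_ordinal(latent_threshold_spec(n = 60, l = 5, P = 5,
                                          noise_sd = 1, seed = 4))
  fit <- svmop(ds, C = 1)
  batch <- predict(fit, ds)
  loop <- vapply(seq_len(nrow(ds$X)),
                 function(i) predict(fit, as.numeric(ds$X[i, ])),
                 integer(1))
  expect_identical(batch, loop)
  expect_true(all(batch >= 1 & batch <= ds$P))
  # empty input gives empty output
  empty <- ds$X[0, , drop = FALSE]
  expect_length(predict(fit, empty), 0)
})

test_that("missing top classes yield degenerate sub-problems with a warning", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40)
  y <- sample(1:2, 40, replace = TRUE)   # P = 3 declared, class 3 absent
  expect_warning(fit <- svmop(X, y, P = 3, C = 1), "single-class")
  expect_length(fit$warnings, 1)
  expect_equal(ncol(fit$W), 2L)
})

test_that("model JSON serialization round-trips exactly", {
  ds <- gen_ordinal(latent_threshold_spec(n = 80, l = 6, P = 4,
                                          noise_sd = 0.5, seed = 13))
  fit <- svmop(ds, C = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  # decimal JSON text can perturb a double by an ulp
  expect_equal(back$W, fit$W, tolerance = 1e-12)
  expect_identical(back$P, fit$P)
  expect_identical(back$bias, fit$bias)
  expect_identical(predict(back, ds), predict(fit, ds))
})

test_that("coef, summary, residuals and plot methods work", {
  ds <- gen_ordinal(latent_threshold_spec(n = 60, l = 4, P = 3,
                                          noise_sd = 0.5, seed = 6))
  fit <- svmop(ds, C = 1)
  W <- coef(fit)
  expect_equal(dim(W), c(5L, 2L))  # 4 features + bias row
  expect_equal(rownames(W)[5], "(bias)")
  s <- summary(fit)
  expect_s3_class(s, "summary.svmop")
  expect_equal(nrow(s$solver), 2)
  r <- residuals(fit, ds)
  expect_identical(r, as.integer(predict(fit, ds)) - ds$y)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, k = 3))
})
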