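# run expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a latent-threshold ordinal generator
#'
#' The standard ordered-probit-style generative model: features are
#' standard normal, a latent score `u = beta'x + eps` is cut by P-1
#' strictly increasing thresholds, and the label is one plus the number of
#' thresholds exceeded. With `noise_sd = 0` the classes are exactly
#' separable by parallel hyperplanes — the geometry the ordinal-
#' partitioning model assumes — so a correct fit reaches training MAE 0.
#'
#' @param n instances.
#' @param l features.
#' @param P ordered categories.
#' @param beta latent direction (length l); default: a fixed draw from the
#'   seed, scaled to unit norm.
#' @param thresholds strictly increasing cutpoints (length P-1); default:
#'   normal quantiles of the latent score making classes equiprobable.
#' @param noise_sd standard deviation of the latent noise.
#' @param margin minimum clearance of the noise-free latent score from
#'   every cutpoint (enforced by rejection). A positive margin makes the
#'   noise-free classes separable by parallel hyperplanes with a finite
#'   geometric margin, so a hard-margin fit exists at finite cost.
#' @param class_balance resample to exactly equal class counts.
#' @param seed integer seed.
#' @return list of class `latent_threshold_spec`.
#' @export
latent_threshold_spec <- function(n = 500L, l = 10L, P = 5L, beta = NULL,
                                  thresholds = NULL, noise_sd = 0,
                                  margin = 0.1, class_balance = FALSE,
                                  seed = 1L) {
  stopifnot(P >= 2L, noise_sd >= 0, margin >= 0, n >= 1L, l >= 1L)
  if (is.null(beta)) {
    beta <- with_seed(seed * 7L + 3L, stats::rnorm(l))
    beta <- beta / sqrt(sum(beta^2))
  }
  if (length(beta) != l) stop("beta must have length l")
  if (is.null(thresholds)) {
    lat_sd <- sqrt(sum(beta^2) + noise_sd^2)
    thresholds <- stats::qnorm(seq_len(P - 1) / P, sd = lat_sd)
  }
  if (length(thresholds) != P - 1 ||
      is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing, length P-1")
  if (margin > 0 && any(diff(c(-Inf, thresholds, Inf)) <= 2 * margin))
    stop("margin too large for the threshold spacing")
  structure(list(n = as.integer(n), l = as.integer(l), P = as.integer(P),
                 beta = beta, thresholds = thresholds, noise_sd = noise_sd,
                 margin = margin, class_balance = isTRUE(class_balance),
                 seed = as.integer(seed)),
            class = "latent_threshold_spec")
}

#' Generate a latent-threshold ordinal dataset
#'
#' The latent direction and cutpoints are fixed by the spec (they were
#' resolved when the spec was built); `seed` only drives the sampling.
#' Drawing twice from one spec with different seeds therefore gives a
#' train/test pair from the same population.
#'
#' @param spec a [latent_threshold_spec()].
#' @param seed sampling seed; defaults to `spec$seed`.
#' @return an [ordinal_dataset()]; reproducible from the seed.
#' @examples
#' spec <- latent_threshold_spec(n = 100, l = 5, P = 3, seed = 42)
#' train <- gen_ordinal(spec)
#' test <- gen_ordinal(spec, seed = 43)  # same population, fresh draw
#' table(train$y)
#' @export
gen_ordinal <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "latent_threshold_spec"))
  draw <- function(m) {
    X <- matrix(0, 0, spec$l)
    u0 <- numeric(0)
    while (nrow(X) < m) {
      Xc <- matrix(stats::rnorm(2L * m * spec$l), ncol = spec$l)
      uc <- as.numeric(Xc %*% spec$beta)
      if (spec$margin > 0) {
        clear <- apply(abs(outer(uc, spec$thresholds, `-`)), 1L,
                       min) >= spec$margin
        Xc <- Xc[clear, , drop = FALSE]
        uc <- uc[clear]
      }
      X <- rbind(X, Xc)
      u0 <- c(u0, uc)
    }
    X <- X[seq_len(m), , drop = FALSE]
    u <- u0[seq_len(m)] +
      if (spec$noise_sd > 0) stats::rnorm(m, sd = spec$noise_sd) else 0
    y <- 1L + rowSums(outer(u, spec$thresholds, `>`))
    list(X = X, y = as.integer(y))
  }
  with_seed(seed, {
    if (!spec$class_balance) {
      d <- draw(spec$n)
    } else {
      per <- spec$n %/% spec$P
      want <- rep(per, spec$P)
      want[seq_len(spec$n - per * spec$P)] <-
        want[seq_len(spec$n - per * spec$P)] + 1L
      got <- vector("list", spec$P)
      have <- integer(spec$P)
      attempts <- 0L
      while (any(have < want)) {
        attempts <- attempts + 1L
        if (attempts > 200L)
          stop("class balancing infeasible: a class has near-zero ",
               "probability under this spec")
        d0 <- draw(max(spec$n, 200L))
        for (cls in seq_len(spec$P)) {
          need <- want[cls] - have[cls]
          if (need <= 0L) next
          idx <- which(d0$y == cls)
          idx <- utils::head(idx, need)
          if (length(idx)) {
            got[[cls]] <- rbind(got[[cls]], d0$X[idx, , drop = FALSE])
            have[cls] <- have[cls] + length(idx)
          }
        }
      }
      X <- do.call(rbind, got)
      y <- rep.int(seq_len(spec$P), want)
      ord <- sample.int(length(y))   # shuffle so folds stay class-mixed
      d <- list(X = X[ord, , drop = FALSE], y = y[ord])
    }
    ordinal_dataset(d$X, d$y, P = spec$P,
                    feature_names = paste0("x", seq_len(spec$l)))
  })
}

#' Specify a synthetic consultation-corpus generator
#'
#' Emulates doctor/patient message threads whose satisfaction label is
#' driven by planted politeness and effort signals: the probability that a
#' doctor token is a politeness term follows a logistic link in the label,
#' the number of doctor turns rises with the label, and the response time
#' to the first question falls with it. With both effects at 0 the text
#' and structure carry no label information. Tokens are opaque ASCII
#' stand-ins; the dictionaries are generated term lists.
#'
#' @param n records.
#' @param dict_sizes integer length-3: symptom, illness, medicine terms.
#' @param politeness_effect log-odds increment per label step for polite
#'   tokens in doctor text.
#' @param effort_effect effect per label step on doctor-turn count (logit
#'   scale) and log response time (negative direction).
#' @param vocab_size generic background vocabulary size.
#' @param seed integer seed.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(n = 200L, dict_sizes = c(30L, 30L, 30L),
                        politeness_effect = 1, effort_effect = 1,
                        vocab_size = 50L, seed = 1L) {
  stopifnot(n >= 1L, length(dict_sizes) == 3L, all(dict_sizes >= 1L),
            is.finite(politeness_effect), is.finite(effort_effect))
  structure(list(n = as.integer(n), dict_sizes = as.integer(dict_sizes),
                 politeness_effect = politeness_effect,
                 effort_effect = effort_effect,
                 vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a synthetic consultation corpus with planted signals
#'
#' @param spec a [corpus_spec()].
#' @return list with `records` (list of [consultation_record()]s, labels in
#'   `1..5`) and `dicts` (a [medical_dictionaries()]).
#' @export
gen_consultations <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    dicts <- medical_dictionaries(
      symptoms = sprintf("sym%03d", seq_len(spec$dict_sizes[1])),
      illnesses = sprintf("ill%03d", seq_len(spec$dict_sizes[2])),
      medicines = sprintf("med%03d", seq_len(spec$dict_sizes[3])))
    generic <- sprintf("w%03d", seq_len(spec$vocab_size))
    polite <- sprintf("polite%02d", 1:5)
    all_med <- c(dicts$symptoms, dicts$illnesses, dicts$medicines)
    records <- lapply(seq_len(spec$n), function(i) {
      y <- sample.int(5L, 1L)
      z <- y - 3L
      # patient side: structure independent of the label
      np <- 1L + stats::rpois(1, 1)
      pat_t <- cumsum(c(0, stats::rexp(np - 1, 1 / 120)))
      pat_text <- vapply(seq_len(np), function(j)
        paste(sample(generic, 3L + stats::rpois(1, 5), replace = TRUE),
              collapse = " "), character(1))
      # doctor side: turn count and response time carry the effort signal
      nd <- stats::rbinom(1, 6L, stats::plogis(0.2 + spec$effort_effect * z / 2))
      doc <- NULL
      if (nd > 0L) {
        rt <- stats::rlnorm(1, meanlog = log(600) - spec$effort_effect * z / 2,
                            sdlog = 0.4)
        doc_t <- pat_t[1] + rt + cumsum(c(0, stats::rexp(nd - 1, 1 / 120)))
        p_polite <- stats::plogis(-1.5 + spec$politeness_effect * z)
        doc_text <- vapply(seq_len(nd), function(j) {
          m <- 4L + stats::rpois(1, 6)
          kind <- stats::runif(m)
          toks <- character(m)
          toks[kind < p_polite] <- sample(polite, sum(kind < p_polite),
                                          replace = TRUE)
          pro <- kind >= p_polite & kind < p_polite + 0.15
          toks[pro] <- sample(all_med, sum(pro), replace = TRUE)
          rest <- !nzchar(toks)
          toks[rest] <- sample(generic, sum(rest), replace = TRUE)
          paste(toks, collapse = " ")
        }, character(1))
        doc <- data.frame(t = doc_t, text = doc_text)
      }
      consultation_record(data.frame(t = pat_t, text = pat_text), doc,
                          label = y)
    })
    list(records = records, dicts = dicts)
  })
}
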