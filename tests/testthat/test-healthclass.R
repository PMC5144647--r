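fixture_lm <- function() {
  train_ngram(lapply(
    generate_health_corpus(corpus_spec(seed = 31, n_tweets = 150,
                                       health_fraction = 1))$text,
    preprocess), n = 4)
}

test_that("batch scaling is the min-max affine map with the degenerate midpoint", {
  m <- fixture_lm()
  texts <- generate_health_corpus(corpus_spec(seed = 32, n_tweets = 40))$text
  sc <- score_batch(m, texts)
  expect_equal(min(sc$scaled), 0)
  expect_equal(max(sc$scaled), 1)
  expect_equal(sc$scaled,
               (sc$raw - min(sc$raw)) / (max(sc$raw) - min(sc$raw)))
  expect_identical(order(sc$scaled), order(sc$raw))
  one <- score_batch(m, texts[1])
  expect_equal(one$scaled, 0.5)
  same <- score_batch(m, rep(texts[1], 3))
  expect_equal(same$scaled, rep(0.5, 3))
  expect_error(score_batch(m, list()), "empty")
})

test_that("length normalization divides by the transition count", {
  m <- fixture_lm()
  toks <- list(c("c001", "c002", "c003"))
  raw_sum <- score_batch(m, toks, normalize = FALSE)$raw
  raw_avg <- score_batch(m, toks, normalize = TRUE)$raw
  expect_equal(raw_avg, raw_sum / 4)
  expect_equal(raw_sum, sequence_logprob(m, toks[[1]]))
})

test_that("threshold classification follows the boundary rules", {
  sc <- tibble::tibble(id = c("a", "b"), raw = c(-1, -9),
                       scaled = c(0.9, 0.1), label = "unlabeled")
  expect_identical(classify(sc, 0.5)$label, c("health", "non-health"))
  expect_identical(classify(sc, 0)$label, c("health", "health"))
  sc3 <- tibble::tibble(id = as.character(1:3), raw = 1:3,
                        scaled = c(0, 0.4, 1), label = "unlabeled")
  expect_identical(classify(sc3, 1)$label, c("non-health", "non-health", "health"))
})

test_that("evaluation metrics hit their closed-form extremes", {
  sc <- tibble::tibble(id = as.character(1:4), raw = c(1, 2, 3, 4),
                       scaled = c(0.9, 0.8, 0.2, 0.1),
                       label = c("health", "health", "non-health", "non-health"))
  gold <- c("health", "health", "non-health", "non-health")
  perfect <- evaluate(sc, gold)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  inverted <- sc
  inverted$label <- rev(sc$label)
  inverted$scaled <- rev(sc$scaled)
  inv <- evaluate(inverted, gold)
  expect_equal(inv$accuracy, 0)
  expect_equal(inv$auc, 0)
  expect_error(evaluate(sc, gold[1:3]), "length")
})

test_that("the tie-aware rank AUC agrees with an independent implementation", {
  set.seed(17)
  scores <- round(runif(60), 1)  # rounding forces ties
  truth <- runif(60) < 0.4
  sc <- tibble::tibble(id = as.character(1:60), raw = scores, scaled = scores,
                       label = ifelse(scores > 0.5, "health", "non-health"))
  ours <- evaluate(sc, ifelse(truth, "health", "non-health"))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("tetra-gram scores separate health from non-health text", {
  train <- generate_health_corpus(corpus_spec(seed = 101, n_tweets = 1200,
                                              health_fraction = 1,
                                              vocab_overlap = 0.8))
  lm <- train_ngram(train, n = 4)
  ev <- generate_health_corpus(corpus_spec(seed = 202, n_tweets = 600,
                                           health_fraction = 0.35,
                                           vocab_overlap = 0.8))
  res <- evaluate(classify(score_batch(lm, ev)), ev$label)
  expect_gt(res$auc, 0.8)
})

test_that("identical class vocabularies leave the classifier at chance", {
  train <- generate_health_corpus(corpus_spec(seed = 41, n_tweets = 1200,
                                              health_fraction = 1,
                                              vocab_overlap = 1))
  lm <- train_ngram(train, n = 4)
  ev <- generate_health_corpus(corpus_spec(seed = 42, n_tweets = 600,
                                           vocab_overlap = 1))
  res <- evaluate(classify(score_batch(lm, ev)), ev$label)
  expect_lt(abs(res$auc - 0.5), 0.1)
})

test_that("disjoint class vocabularies separate almost perfectly", {
  train <- generate_health_corpus(corpus_spec(seed = 51, n_tweets = 1200,
                                              health_fraction = 1,
                                              vocab_overlap = 0))
  lm <- train_ngram(train, n = 4)
  ev <- generate_health_corpus(corpus_spec(seed = 52, n_tweets = 600,
                                           vocab_overlap = 0))
  res <- evaluate(classify(score_batch(lm, ev)), ev$label)
  expect_gte(res$auc, 0.95)
})
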