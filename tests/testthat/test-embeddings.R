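# Small corpus with one strongly planted co-occurrence pair and one token
# that never co-occurs with the drug.
planted_corpus <- function(seed = 42) {
  set.seed(seed)
  c(
    lapply(1:250, function(i) c(sample(c("drugx", "nausea"), 2),
                                sample(sprintf("w%02d", 1:30), 6, TRUE))),
    lapply(1:250, function(i) c("umbrella",
                                sample(sprintf("w%02d", 1:30), 7, TRUE)))
  )
}

test_that("trained vectors have the requested shape and finite entries", {
  m <- train_skipgram(planted_corpus(), dim = 8, window = 2, epochs = 1, seed = 1)
  expect_identical(dim(m$vectors), c(length(m$vocab), 8L))
  expect_true(all(is.finite(m$vectors)))
  expect_true(all(is.finite(m$loss)))
  expect_identical(rownames(m$vectors), m$vocab)
  expect_error(train_skipgram(list(), dim = 8), "empty")
  expect_error(train_skipgram(planted_corpus(), dim = 8, min_count = 1000),
               "min_count")
})

test_that("training is bitwise deterministic given a seed", {
  corp <- planted_corpus()
  a <- train_skipgram(corp, dim = 8, window = 2, epochs = 2, seed = 3)
  b <- train_skipgram(corp, dim = 8, window = 2, epochs = 2, seed = 3)
  expect_identical(a$vectors, b$vectors)
  expect_identical(a$loss, b$loss)
  c_ <- train_skipgram(corp, dim = 8, window = 2, epochs = 2, seed = 4)
  expect_false(identical(a$vectors, c_$vectors))
})

test_that("a planted co-occurrence pair outscores a never-co-occurring token", {
  corp <- planted_corpus()
  wins <- 0L
  for (s in 1:10) {
    m <- train_skipgram(corp, dim = 16, window = 2, epochs = 5, seed = s)
    cs <- function(a, b) cosine_similarity(m$vectors[a, ], m$vectors[b, ])
    if (cs("drugx", "nausea") > cs("drugx", "umbrella")) wins <- wins + 1L
    if (s == 1) {
      nn <- nearest_neighbors(m, "drugx", 3)
      expect_true("nausea" %in% nn$token)
    }
  }
  expect_gte(wins, 9L)
})

test_that("cosine similarity satisfies its defining identities", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 4)), 1)
  expect_equal(cosine_similarity(c(1, 1), c(1, -1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  set.seed(9)
  for (i in 1:20) {
    u <- rnorm(6)
    v <- rnorm(6)
    s <- runif(1, 0.1, 10)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
    expect_equal(cosine_similarity(u, v), cosine_similarity(s * u, v))
    expect_gte(cosine_similarity(u, v), -1)
    expect_lte(cosine_similarity(u, v), 1)
  }
})

test_that("nearest neighbours are ranked, exclude the query and reject OOV", {
  M <- rbind(alpha = c(1, 0), beta = c(0.9, 0.1))
  toy <- structure(list(vectors = M, vocab = rownames(M),
                        hyperparameters = list(dim = 2)),
                   class = "embedding_model")
  nn <- nearest_neighbors(toy, "alpha", 1)
  expect_identical(nn$token, "beta")
  m <- train_skipgram(planted_corpus(), dim = 8, window = 2, epochs = 1, seed = 1)
  nn2 <- nearest_neighbors(m, "drugx", 10)
  expect_false("drugx" %in% nn2$token)
  expect_true(all(diff(nn2$similarity) <= 1e-12))
  expect_error(nearest_neighbors(m, "notaword", 3), "notaword")
})

test_that("word2vec text round-trip preserves vectors within 1e-6", {
  m <- train_skipgram(planted_corpus(), dim = 5, window = 2, epochs = 1, seed = 2)
  f <- tempfile(fileext = ".vec")
  save_word2vec_text(m, f)
  m2 <- load_word2vec_text(f)
  expect_lt(max(abs(m$vectors - m2$vectors[rownames(m$vectors), ])), 1e-6)
  hdr <- as.integer(strsplit(readLines(f, n = 1), " ")[[1]])
  expect_identical(hdr[1], length(m$vocab))
  expect_identical(hdr[1] + 1L, length(readLines(f)))
})

test_that("hand-written word2vec files load verbatim and bad files name the line", {
  f <- tempfile(fileext = ".vec")
  writeLines(c("2 3", "cat 0.1 0.2 0.3", "dog -1 0 2.5"), f)
  m <- load_word2vec_text(f)
  expect_equal(unname(m$vectors["cat", ]), c(0.1, 0.2, 0.3))
  expect_equal(unname(m$vectors["dog", ]), c(-1, 0, 2.5))
  f2 <- tempfile(fileext = ".vec")
  writeLines(c("2 3", "cat 0.1 0.2 0.3"), f2)
  expect_error(load_word2vec_text(f2), "header says 2")
  f3 <- tempfile(fileext = ".vec")
  writeLines(c("1 3", "cat 0.1 0.2"), f3)
  expect_error(load_word2vec_text(f3), "line 2")
})
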