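# Shared test helpers: independent oracles and small generated fixtures.

# Brute-force enumeration of every string at edit distance exactly 1 from
# `word` over `alphabet` (plus the word's own letters), using utils::adist
# as the distance oracle — independent of the package's DP implementation.
brute_force_variants <- function(word, alphabet) {
  chars <- unique(c(alphabet, strsplit(word, "", fixed = TRUE)[[1]]))
  lens <- (nchar(word) - 1L):(nchar(word) + 1L)
  cand <- unlist(lapply(lens[lens >= 1L], function(L) {
    grid <- do.call(expand.grid, c(rep(list(chars), L), stringsAsFactors = FALSE))
    do.call(paste0, grid)
  }))
  cand <- unique(cand)
  sort(cand[as.integer(utils::adist(word, cand)) == 1L])
}

# A tiny deterministic tweet tibble.
toy_tweets <- function() {
  tibble::tibble(
    id = c("1", "2", "3"),
    created_at = lubridate::ymd_hms(c("2014-11-02 10:00:00", "2014-11-20 11:30:00",
                                      "2014-12-05 09:15:00"), tz = "UTC"),
    text = c("Just took my Adderall!!", "umbrella weather today",
             "xanax and adderal again")
  )
}

write_jsonl_fixture <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path)
  path
}

# A hand-built embedding model with known cosine geometry.
stub_embedding <- function(cosines) {
  # cosines: named numeric; cosine of each token with the token "drug"
  toks <- c("drug", names(cosines))
  M <- rbind(c(1, 0),
             t(vapply(cosines, function(s) c(s, sqrt(1 - s^2)), numeric(2))))
  rownames(M) <- toks
  structure(list(vectors = M, input_vectors = NULL, context_vectors = NULL,
                 vocab = toks, frequencies = NULL, loss = NULL,
                 hyperparameters = list(dim = 2)),
            class = "embedding_model")
}

# Random small token corpus over a tiny vocabulary.
random_small_corpus <- function(n_sentences = 5, vocab = letters[1:5],
                                max_len = 7) {
  lapply(seq_len(n_sentences), function(i) {
    sample(vocab, sample(2:max_len, 1), replace = TRUE)
  })
}

# Every context observed in a model's stored tables, per order.
observed_contexts <- function(model) {
  ctxs <- list(character(0))
  for (k in seq_len(model$n - 1L)) {
    keys <- ls(model$bow[[k]])
    ctxs <- c(ctxs, lapply(keys, function(g) strsplit(g, " ", fixed = TRUE)[[1]]))
  }
  ctxs
}

# Max |1 - sum_w P(w|c)| over all observed contexts of a model.
max_normalization_error <- function(model) {
  errs <- vapply(observed_contexts(model), function(cx) {
    abs(1 - sum(vapply(model$vocab, function(w) {
      cond_prob(model, w, cx, log = FALSE)
    }, numeric(1))))
  }, numeric(1))
  max(errs)
}
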