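#' Train skip-gram word embeddings
#'
#' Learns dense distributed word representations by training a shallow
#' two-layer network to predict, for each input term, the terms inside a
#' symmetric context window around it (skip-gram with negative sampling;
#' the negative-sampling noise distribution is the unigram distribution
#' raised to the 0.75 power). Training is single-threaded and deterministic
#' given `seed`: the same corpus and hyperparameters reproduce bitwise
#' identical vectors. Reference-scale models use `dim` 200-400 with windows
#' up to 9; tests and examples use small dimensions.
#'
#' @param corpus List of character token vectors, or a tweet tibble with a
#'   `text` column (tokenized via [preprocess()]).
#' @param dim Vector dimension (>= 2).
#' @param window Symmetric context window half-width (>= 1). The window is
#'   fixed (no random shrinking) so runs are reproducible; set
#'   `dynamic_window = TRUE` for word2vec-style random shrinking.
#' @param negative Negative samples per positive example.
#' @param epochs Training passes over the corpus.
#' @param alpha Initial learning rate (decays linearly to `alpha/10000`).
#' @param min_count Drop tokens rarer than this from the vocabulary.
#' @param seed RNG seed for initialization and negative sampling.
#' @param dynamic_window If `TRUE`, the effective window at each position is
#'   drawn uniformly from 1..`window` (breaks exact reproducibility across
#'   implementations; off by default).
#' @return An `embedding_model`: list with `vectors` (V x dim matrix, rows
#'   named by token; the sum of the input and context matrices, which also
#'   carries direct co-occurrence similarity), `input_vectors`,
#'   `context_vectors`, `vocab`, `hyperparameters`, and per-epoch training
#'   `loss`.
#' @export
train_skipgram <- function(corpus, dim = 100, window = 5, negative = 5,
                           epochs = 5, alpha = 0.025, min_count = 1,
                           seed = 1, dynamic_window = FALSE) {
  if (is.data.frame(corpus)) corpus <- lapply(corpus$text, preprocess)
  corpus <- corpus[lengths(corpus) > 0L]
  if (length(corpus) == 0L) stop("training corpus is empty", call. = FALSE)
  stopifnot(dim >= 2, window >= 1, negative >= 0, epochs >= 1)
  counts <- table(unlist(corpus))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) {
    stop("no tokens survive min_count pruning", call. = FALSE)
  }
  vocab <- sort(names(counts))
  freq <- as.numeric(counts[vocab])
  index <- setNames(seq_along(vocab) - 1L, vocab)
  sent_ids <- lapply(corpus, function(s) {
    i <- index[s]
    as.integer(i[!is.na(i)])
  })
  sent_ids <- sent_ids[lengths(sent_ids) > 0L]

  noise <- freq^0.75
  noise_cdf <- cumsum(noise) / sum(noise)

  fit <- .sgns_train(sent_ids, length(vocab), as.integer(dim),
                     as.integer(window), as.integer(negative),
                     as.integer(epochs), alpha, alpha / 1e4,
                     noise_cdf, as.integer(seed), isTRUE(dynamic_window))
  W <- fit$word
  C <- fit$context
  rownames(W) <- rownames(C) <- vocab
  if (any(!is.finite(W)) || any(!is.finite(C))) {
    stop("training produced non-finite vectors", call. = FALSE)
  }
  # The exposed representation sums the input and context matrices: the
  # summed embedding carries both paradigmatic (shared-context) and
  # syntagmatic (direct co-occurrence) similarity, which is what
  # drug/adverse-reaction association signals need.
  structure(
    list(
      vectors = W + C, input_vectors = W, context_vectors = C, vocab = vocab,
      frequencies = setNames(freq, vocab),
      loss = fit$epoch_loss,
      hyperparameters = list(dim = dim, window = window, negative = negative,
                             epochs = epochs, alpha = alpha,
                             min_count = min_count, seed = seed)
    ),
    class = "embedding_model"
  )
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length; neither may be all zeros.
#' @return u.v / (|u||v|), in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector",
                               call. = FALSE)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

word_vector <- function(model, token) {
  if (!token %in% model$vocab) {
    stop("token not in embedding vocabulary: ", dQuote(token), call. = FALSE)
  }
  model$vectors[token, ]
}

#' Nearest neighbours of a token in embedding space
#'
#' @param model An [train_skipgram()] model.
#' @param token Query token (must be in vocabulary).
#' @param k Number of neighbours.
#' @return Tibble `token`, `similarity`, sorted by decreasing similarity
#'   (ties broken lexicographically); the query itself is excluded.
#' @export
nearest_neighbors <- function(model, token, k = 10) {
  stopifnot(inherits(model, "embedding_model"), k >= 1)
  q <- word_vector(model, token)
  M <- model$vectors
  sims <- as.numeric(M %*% q) / (sqrt(rowSums(M^2)) * sqrt(sum(q^2)))
  out <- tibble::tibble(token = rownames(M), similarity = sims) |>
    dplyr::filter(.data$token != !!token) |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$token)
  head(out, k)
}

#' @export
print.embedding_model <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf(
    "<embedding_model> %d tokens x %d dims (window %d, %d negatives, %d epochs, seed %d)\n",
    length(x$vocab), h$dim, h$window, h$negative, h$epochs, h$seed))
  invisible(x)
}

#' Tidy an embedding model into long form
#'
#' @param x An `embedding_model`.
#' @param ... Unused.
#' @return Tibble `token`, `dimension`, `value`.
#' @export
tidy.embedding_model <- function(x, ...) {
  tibble::as_tibble(x$vectors, rownames = "token") |>
    tidyr::pivot_longer(-"token", names_to = "dimension", values_to = "value") |>
    dplyr::mutate(dimension = as.integer(sub("^V", "", .data$dimension)))
}

#' One-row summary of an embedding model
#'
#' @param x An `embedding_model`.
#' @param ... Unused.
#' @export
glance.embedding_model <- function(x, ...) {
  h <- x$hyperparameters
  tibble::tibble(
    vocab_size = length(x$vocab), dim = h$dim, window = h$window,
    negative = h$negative, epochs = h$epochs, seed = h$seed,
    final_loss = x$loss[length(x$loss)]
  )
}

#' Write embeddings in word2vec text format
#'
#' Header line `V d`, then one `token v1 ... vd` line per vocabulary token.
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_word2vec_text <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  M <- model$vectors
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(rownames(M)[i], format(M[i, ], digits = 12, trim = TRUE,
                                   scientific = FALSE)), collapse = " ")
  }, character(1))
  writeLines(c(sprintf("%d %d", nrow(M), ncol(M)), body), path, useBytes = TRUE)
  invisible(path)
}

#' Read embeddings in word2vec text format
#'
#' @param path Path to a word2vec text file.
#' @return An `embedding_model` (hyperparameters unknown except `dim`).
#' @export
load_word2vec_text <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- strsplit(trimws(lines[1]), " +")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("word2vec parse error at line 1: expected header 'V d'", call. = FALSE)
  }
  V <- as.integer(hdr[1])
  d <- as.integer(hdr[2])
  if (length(lines) - 1L != V) {
    stop("word2vec parse error: header says ", V, " tokens but file has ",
         length(lines) - 1L, call. = FALSE)
  }
  M <- matrix(NA_real_, V, d)
  toks <- character(V)
  for (i in seq_len(V)) {
    parts <- strsplit(trimws(lines[i + 1L]), " +")[[1]]
    if (length(parts) != d + 1L) {
      stop("word2vec parse error at line ", i + 1L, ": expected ", d + 1L,
           " fields, found ", length(parts), call. = FALSE)
    }
    toks[i] <- parts[1]
    M[i, ] <- as.numeric(parts[-1])
  }
  if (anyNA(M)) stop("word2vec parse error: non-numeric vector entries", call. = FALSE)
  rownames(M) <- toks
  structure(
    list(vectors = M, input_vectors = NULL, context_vectors = NULL, vocab = toks,
         frequencies = NULL, loss = NULL,
         hyperparameters = list(dim = d, window = NA, negative = NA,
                                epochs = NA, alpha = NA, min_count = NA, seed = NA)),
    class = "embedding_model"
  )
}
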