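# Sentence markers. The start marker is never a predicted outcome; the end
# marker and the unknown symbol are first-class members of the prediction
# vocabulary, so every trained model is a proper distribution over sentences.
NGRAM_BOS <- "<s>"
NGRAM_EOS <- "</s>"
NGRAM_UNK <- "<unk>"

new_hash <- function() new.env(hash = TRUE, parent = emptyenv())

hash_from <- function(keys, values) {
  e <- new_hash()
  for (i in seq_along(keys)) assign(keys[i], values[[i]], envir = e)
  e
}

hash_get <- function(e, key, default = NULL) {
  v <- get0(key, envir = e, inherits = FALSE)
  if (is.null(v)) default else v
}

# k-gram count table (named numeric) over padded sentences; grams whose
# final token is the start marker are excluded (never predicted).
count_kgrams <- function(padded, k) {
  grams <- unlist(lapply(padded, function(s) {
    m <- length(s)
    if (m < k) return(character(0))
    idx <- seq_len(m - k + 1L)
    g <- vapply(idx, function(i) paste(s[i:(i + k - 1L)], collapse = " "), character(1))
    last <- vapply(idx, function(i) s[i + k - 1L], character(1))
    g[last != NGRAM_BOS]
  }))
  if (length(grams) == 0L) return(setNames(numeric(0), character(0)))
  tab <- table(grams)
  setNames(as.numeric(tab), names(tab))
}

gram_first <- function(keys) sub(" .*$", "", keys)
gram_rest <- function(keys) sub("^[^ ]+ ", "", keys)
gram_context <- function(keys) sub(" [^ ]+$", "", keys)
gram_last <- function(keys) sub("^.* ", "", keys)

#' Train an order-n language model on tokenized text
#'
#' Estimates an n-gram model (n in 2..4) of token-sequence probabilities
#' P(w1..wm) = prod_k P(wk | preceding n-1 tokens). Each sentence is padded
#' with n-1 start markers and one end marker; tokens seen fewer than
#' `min_count` times are replaced by an unknown symbol that stays in the
#' vocabulary, so arbitrary text can be scored. The default estimator is
#' interpolated Kneser-Ney smoothing with a single absolute discount
#' (lower-order distributions use continuation counts, and discounted mass
#' is spread over the lower order); `smoothing = "mle"` gives raw
#' count-ratio estimates for hand-checkable diagnostics.
#'
#' @param corpus A list of character token vectors (one per sentence/post),
#'   or a tweet tibble with a `text` column (tokenized via [preprocess()]).
#' @param n Model order, 2 to 4 (4 = "tetra-gram").
#' @param min_count Tokens rarer than this become the unknown symbol
#'   (default 1: no replacement).
#' @param smoothing `"kn"` (interpolated Kneser-Ney, default) or `"mle"`.
#' @param discount Absolute discount D in (0,1), default 0.75.
#' @return An `ngram_model` object.
#' @examples
#' m <- train_ngram(list(c("a", "b", "a", "b", "a")), n = 2, smoothing = "mle")
#' exp(cond_prob(m, "b", "a")) # 2/3
#' @export
train_ngram <- function(corpus, n, min_count = 1, smoothing = c("kn", "mle"),
                        discount = 0.75) {
  smoothing <- match.arg(smoothing)
  if (is.data.frame(corpus)) corpus <- lapply(corpus$text, preprocess)
  corpus <- corpus[lengths(corpus) > 0L]
  if (length(corpus) == 0L) stop("training corpus is empty", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n > 4) {
    stop("`n` must be an integer in [2, 4]", call. = FALSE)
  }
  n <- as.integer(n)
  if (smoothing == "kn" && (discount <= 0 || discount >= 1)) {
    stop("`discount` must lie in (0, 1)", call. = FALSE)
  }

  uni <- table(unlist(corpus))
  rare <- names(uni)[uni < min_count]
  if (length(rare)) {
    corpus <- lapply(corpus, function(s) ifelse(s %in% rare, NGRAM_UNK, s))
  }
  vocab <- sort(unique(c(unlist(corpus), NGRAM_EOS, NGRAM_UNK)))
  padded <- lapply(corpus, function(s) c(rep(NGRAM_BOS, n - 1L), s, NGRAM_EOS))

  raw <- lapply(seq_len(n), function(k) count_kgrams(padded, k))

  # Adjusted counts: highest order and start-marker-initial grams keep raw
  # counts; other lower-order grams use continuation counts (number of
  # distinct extending predecessors), the Kneser-Ney construction.
  adj <- raw
  if (smoothing == "kn") {
    for (k in seq_len(n - 1L)) {
      hi <- names(raw[[k + 1L]])
      cont <- table(gram_rest(hi))
      ak <- setNames(as.numeric(cont), names(cont))
      keys <- union(names(raw[[k]]), names(ak))
      bos_first <- startsWith(keys, paste0(NGRAM_BOS, " ")) | keys == NGRAM_BOS
      vals <- ifelse(bos_first,
                     ifelse(is.na(raw[[k]][keys]), 0, raw[[k]][keys]),
                     ifelse(is.na(ak[keys]), 0, ak[keys]))
      adj[[k]] <- setNames(as.numeric(vals), keys)
      adj[[k]] <- adj[[k]][adj[[k]] > 0]
    }
  }

  D <- if (smoothing == "kn") discount else 0
  prob <- vector("list", n)
  bow <- vector("list", n)   # bow[[k]] holds weights for order-k contexts

  # Unigram level.
  u <- adj[[1L]]
  u <- u[names(u) %in% vocab]
  tot <- sum(u)
  V <- length(vocab)
  p1 <- setNames(numeric(V), vocab)
  if (smoothing == "kn") {
    gamma1 <- D * length(u) / tot
    seen <- ifelse(is.na(u[vocab]), 0, u[vocab])
    p1[] <- pmax(seen - D, 0) / tot + gamma1 / V
  } else {
    p1[] <- ifelse(is.na(u[vocab]), 0, u[vocab]) / tot
    p1 <- p1[p1 > 0]
  }
  prob[[1L]] <- hash_from(names(p1), log(p1))

  # Higher orders, bottom-up so the interpolation term can be looked up.
  model <- structure(
    list(n = n, smoothing = smoothing, discount = D, min_count = min_count,
         vocab = vocab, prob = prob, bow = bow, counts = raw),
    class = "ngram_model"
  )
  for (k in 2:n) {
    tab <- adj[[k]]
    ctx <- gram_context(names(tab))
    w <- gram_last(names(tab))
    den <- tapply(tab, ctx, sum)
    types <- tapply(tab, ctx, length)
    model$bow[[k - 1L]] <- if (smoothing == "kn") {
      hash_from(names(den), log(D * types[names(den)] / den))
    } else {
      hash_from(names(den), rep(0, length(den)))  # diagnostic: unweighted backoff
    }
    pvals <- numeric(length(tab))
    if (smoothing == "kn") {
      lower <- vapply(seq_along(tab), function(i) {
        ctx_toks <- strsplit(ctx[i], " ", fixed = TRUE)[[1]]
        lp_lookup(model, w[i], ctx_toks[-1L], k - 1L)
      }, numeric(1))
      gamma <- (D * types[ctx] / den[ctx])
      pvals <- pmax(tab - D, 0) / den[ctx] + gamma * exp(lower)
    } else {
      pvals <- tab / den[ctx]
    }
    model$prob[[k]] <- hash_from(names(tab), log(pvals))
  }
  model
}

# Backoff log-probability lookup: longest stored gram wins; otherwise the
# context's backoff weight (1 if the context was never seen) times the
# lower-order estimate. Tokens are assumed already mapped into the vocab.
lp_lookup <- function(model, word, ctx, k = length(ctx) + 1L) {
  key <- if (k == 1L) word else paste(c(ctx, word), collapse = " ")
  p <- hash_get(model$prob[[k]], key)
  if (!is.null(p)) return(p)
  if (k == 1L) {
    p <- hash_get(model$prob[[1L]], NGRAM_UNK)
    if (is.null(p)) stop("token has no unigram probability: ", word, call. = FALSE)
    return(p)
  }
  b <- hash_get(model$bow[[k - 1L]], paste(ctx, collapse = " "), default = 0)
  b + lp_lookup(model, word, ctx[-1L], k - 1L)
}

map_to_vocab <- function(model, tokens) {
  ifelse(tokens %in% model$vocab | tokens == NGRAM_BOS, tokens, NGRAM_UNK)
}

#' Conditional log-probability of a word given its context
#'
#' The context is truncated to the model's last n-1 tokens; out-of-vocabulary
#' tokens (in the word or the context) are mapped to the unknown symbol.
#' Under Kneser-Ney smoothing the result is strictly positive probability
#' mass for every word in the vocabulary, with interpolation/backoff for
#' unseen histories.
#'
#' @param model An [train_ngram()] model.
#' @param word A single token (use `"</s>"` for the end-of-sentence event).
#' @param context Character vector of preceding tokens (may be empty).
#' @param log If `FALSE`, return the probability instead of its natural log.
#' @return Natural-log probability (default) or probability.
#' @export
cond_prob <- function(model, word, context = character(0), log = TRUE) {
  stopifnot(inherits(model, "ngram_model"), length(word) == 1L)
  word <- map_to_vocab(model, word)
  context <- map_to_vocab(model, context)
  keep <- model$n - 1L
  if (length(context) > keep) {
    context <- if (keep == 0L) character(0) else
      context[(length(context) - keep + 1L):length(context)]
  }
  lp <- lp_lookup(model, word, context)
  if (log) lp else exp(lp)
}

#' Log-probability of a token sequence
#'
#' Chain-rule score of a sentence: the sum over tokens (and the final
#' end-marker transition) of the conditional log-probability given the n-1
#' preceding tokens, with start-marker padding. Natural log.
#'
#' @param model An `ngram_model`.
#' @param tokens Character vector of tokens (may be empty: the score of an
#'   immediately ending sentence).
#' @return The natural-log probability of the sequence.
#' @export
sequence_logprob <- function(model, tokens) {
  stopifnot(inherits(model, "ngram_model"))
  seq_ <- c(rep(NGRAM_BOS, model$n - 1L), map_to_vocab(model, tokens), NGRAM_EOS)
  start <- model$n
  total <- 0
  for (i in start:length(seq_)) {
    ctx <- if (model$n > 1L) seq_[(i - model$n + 1L):(i - 1L)] else character(0)
    total <- total + lp_lookup(model, seq_[i], ctx)
  }
  total
}

#' Perplexity of a corpus under a model
#'
#' exp of the average negative log-probability per scored transition
#' (end-marker transitions included); lower is a better fit.
#'
#' @param model An `ngram_model`.
#' @param corpus List of token vectors, or a tweet tibble with `text`.
#' @return A number >= 1 (up to smoothing, for proper models).
#' @export
perplexity <- function(model, corpus) {
  if (is.data.frame(corpus)) corpus <- lapply(corpus$text, preprocess)
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  lp <- vapply(corpus, function(s) sequence_logprob(model, s), numeric(1))
  transitions <- sum(lengths(corpus) + 1L)
  exp(-sum(lp) / transitions)
}

#' @export
print.ngram_model <- function(x, ...) {
  sizes <- vapply(x$prob, function(e) length(ls(e)), integer(1))
  cat(sprintf("<ngram_model> order %d (%s), vocabulary %d\n",
              x$n, x$smoothing, length(x$vocab)))
  cat("  stored n-grams:", paste(sprintf("%d:%d", seq_along(sizes), sizes),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an n-gram model into its stored probabilities
#'
#' @param x An `ngram_model`.
#' @param ... Unused.
#' @return A tibble with `order`, `gram`, `log_prob` (natural log) and
#'   `log_bow` (backoff weight, NA where none is stored).
#' @export
tidy.ngram_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n), function(k) {
    keys <- sort(ls(x$prob[[k]]))
    bows <- if (k < x$n && !is.null(x$bow[[k]])) {
      vapply(keys, function(g) {
        b <- hash_get(x$bow[[k]], g)
        if (is.null(b)) NA_real_ else b
      }, numeric(1))
    } else {
      rep(NA_real_, length(keys))
    }
    tibble::tibble(
      order = k, gram = keys,
      log_prob = vapply(keys, function(g) hash_get(x$prob[[k]], g), numeric(1)),
      log_bow = unname(bows)
    )
  })
}

#' One-row summary of an n-gram model
#'
#' @param x An `ngram_model`.
#' @param ... Unused.
#' @export
glance.ngram_model <- function(x, ...) {
  tibble::tibble(
    order = x$n, smoothing = x$smoothing, discount = x$discount,
    vocab_size = length(x$vocab),
    n_grams = sum(vapply(x$prob, function(e) length(ls(e)), integer(1)))
  )
}
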