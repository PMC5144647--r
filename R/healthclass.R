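#' Score a batch of texts with an n-gram model
#'
#' Computes, for each text, its sequence log-probability under the model
#' (by default the per-transition average, so length alone does not drive
#' the ranking) and min-max scales the raw scores over the batch into
#' [0, 1]. Scaling is a monotone affine map, so the scaled ordering equals
#' the raw ordering; a degenerate batch in which all raw scores coincide
#' maps to 0.5.
#'
#' @param model An [train_ngram()] model (order 4, a "tetra-gram", for the
#'   reference health-text application).
#' @param texts List of token vectors, a character vector of raw texts
#'   (tokenized via [preprocess()]), or a tweet tibble with `text`.
#' @param normalize If `TRUE` (default) the raw score is the mean
#'   log-probability per transition; if `FALSE` the plain sum.
#' @return A `scored_text` tibble: `id`, `raw`, `scaled`, `label`
#'   (initially `"unlabeled"`).
#' @export
score_batch <- function(model, texts, normalize = TRUE) {
  stopifnot(inherits(model, "ngram_model"))
  if (is.data.frame(texts)) {
    ids <- as.character(texts$id)
    toks <- lapply(texts$text, preprocess)
  } else if (is.character(texts)) {
    ids <- as.character(seq_along(texts))
    toks <- lapply(texts, preprocess)
  } else {
    ids <- as.character(seq_along(texts))
    toks <- texts
  }
  if (length(toks) == 0L) stop("batch is empty", call. = FALSE)
  raw <- vapply(seq_along(toks), function(i) {
    lp <- sequence_logprob(model, toks[[i]])
    if (normalize) lp / (length(toks[[i]]) + 1L) else lp
  }, numeric(1))
  rng <- range(raw)
  scaled <- if (rng[1] == rng[2]) {
    rep(0.5, length(raw))
  } else {
    (raw - rng[1]) / (rng[2] - rng[1])
  }
  out <- tibble::tibble(id = ids, raw = raw, scaled = scaled,
                        label = "unlabeled")
  class(out) <- c("scored_text", class(out))
  out
}

#' Threshold scored texts into health / non-health
#'
#' A text is labelled health-related iff its scaled score is at least
#' `threshold` — texts resembling the (health-domain) training corpus of
#' the language model score higher.
#'
#' @param scored A [score_batch()] result.
#' @param threshold Scaled-score cutoff in [0, 1].
#' @return `scored` with `label` set to `"health"` / `"non-health"`.
#' @export
classify <- function(scored, threshold = 0.5) {
  stopifnot(is.data.frame(scored), threshold >= 0, threshold <= 1)
  scored$label <- ifelse(scored$scaled >= threshold, "health", "non-health")
  scored
}

# Rank-based AUC with ties counted 1/2 (Mann-Whitney statistic).
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)  # mid-ranks handle ties as 1/2
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate health-text predictions against gold labels
#'
#' Standard binary metrics; AUC is the rank statistic over scaled scores
#' with ties counted 1/2, so it is threshold-free.
#'
#' @param scored A classified [score_batch()] result (labels set).
#' @param gold Character or logical vector of gold labels, same length;
#'   `"health"`/`TRUE` is the positive class.
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `n`.
#' @export
evaluate <- function(scored, gold) {
  if (nrow(scored) != length(gold)) {
    stop("predictions and gold labels differ in length", call. = FALSE)
  }
  pos <- if (is.logical(gold)) gold else gold == "health"
  pred <- scored$label == "health"
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(
    accuracy = mean(pred == pos),
    precision = precision, recall = recall, f1 = f1,
    auc = rank_auc(scored$scaled, pos),
    n = length(pos)
  )
}

#' Plot the score distributions of health vs other texts
#'
#' @param object A `scored_text` tibble whose `label` column is populated
#'   (via [classify()] or by assigning gold labels).
#' @param ... Unused.
#' @export
autoplot.scored_text <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scaled, fill = .data$label)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6, bins = 30) +
    ggplot2::labs(x = "scaled language-model score", y = "texts",
                  title = "Language-model scores by class")
}
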