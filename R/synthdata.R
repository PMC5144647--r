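#' Specification of a synthetic drug-chatter corpus
#'
#' Describes the generating process for a synthetic tweet corpus with the
#' statistical structure the rest of the toolkit assumes: posts over a
#' four-month window, a controllable fraction mentioning a drug keyword
#' (sometimes misspelled with a phonetically equal variant), adverse-reaction
#' terms planted next to the drug mention at set co-occurrence rates, decoy
#' terms that occur only away from drug mentions, and heavy-tailed (Zipf)
#' background vocabulary with negative-binomial post lengths.
#'
#' @param seed RNG seed; the whole corpus is deterministic given the spec.
#' @param n_tweets Number of posts (>= 1).
#' @param drugs Character vector of drug keywords.
#' @param mention_rate Probability a post mentions a drug.
#' @param misspelling_rate Probability a drug mention is replaced by one of
#'   its phonetically equal one-edit variants (generator stage 2).
#' @param planted_pairs Tibble/data frame `drug`, `term`, `prob`: each
#'   drug-mentioning post includes `term` adjacent to the drug with
#'   probability `prob`.
#' @param decoy_terms Terms planted only in posts without a drug mention, so
#'   they occur in the corpus but never co-occur with a drug.
#' @param decoy_rate Per-term inclusion probability in non-mention posts.
#' @param background_vocab Background vocabulary size (Zipf exponent 1.1).
#' @param health_fraction Positive-class fraction for
#'   [generate_health_corpus()] (reference labeled sets run about 35%
#'   health-related).
#' @param vocab_overlap Fraction (delta) of content word types shared
#'   between the health and non-health vocabularies: 1 makes the two
#'   label-conditional distributions identical, 0 makes them disjoint.
#' @param class_vocab Content vocabulary size per class for the health
#'   corpus.
#' @param length_mean,length_dispersion Negative-binomial post-length
#'   parameters (mean tokens per post; dispersion = NB size).
#' @param date_range Character vector of two dates (inclusive window for
#'   uniform timestamps); default the four months Nov 2014 - Feb 2015.
#' @return A `corpus_spec` object (validated list).
#' @export
corpus_spec <- function(seed = 1,
                        n_tweets = 2000,
                        drugs = c("adderall", "xanax", "seroquel"),
                        mention_rate = 0.5,
                        misspelling_rate = 0.1,
                        planted_pairs = NULL,
                        decoy_terms = character(0),
                        decoy_rate = 0.3,
                        background_vocab = 500,
                        health_fraction = 0.35,
                        vocab_overlap = 0.8,
                        class_vocab = 200,
                        length_mean = 12,
                        length_dispersion = 5,
                        date_range = c("2014-11-01", "2015-02-28")) {
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble::tibble(drug = character(), term = character(),
                                    prob = numeric())
  }
  planted_pairs <- tibble::as_tibble(planted_pairs)
  spec <- structure(
    list(seed = seed, n_tweets = n_tweets, drugs = tolower(drugs),
         mention_rate = mention_rate, misspelling_rate = misspelling_rate,
         planted_pairs = planted_pairs, decoy_terms = tolower(decoy_terms),
         decoy_rate = decoy_rate, background_vocab = background_vocab,
         health_fraction = health_fraction, vocab_overlap = vocab_overlap,
         class_vocab = class_vocab, length_mean = length_mean,
         length_dispersion = length_dispersion, date_range = date_range),
    class = "corpus_spec"
  )
  validate_corpus_spec(spec)
  spec
}

validate_corpus_spec <- function(spec) {
  probs <- c(spec$mention_rate, spec$misspelling_rate, spec$decoy_rate,
             spec$health_fraction, spec$vocab_overlap, spec$planted_pairs$prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities in a corpus_spec must lie in [0, 1]", call. = FALSE)
  }
  if (spec$n_tweets < 1) stop("n_tweets must be >= 1", call. = FALSE)
  bad <- setdiff(tolower(spec$planted_pairs$drug), spec$drugs)
  if (length(bad)) {
    stop("planted pair(s) reference undeclared drug(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

zipf_probs <- function(n, exponent = 1.1) {
  p <- 1 / seq_len(n)^exponent
  p / sum(p)
}

nb_length <- function(n, mean, dispersion, min_len = 3L) {
  pmax(min_len, rnbinom(n, size = dispersion, mu = mean))
}

#' Generate a synthetic drug-chatter corpus
#'
#' Deterministic given the spec's seed. Each post draws its length from a
#' negative binomial, its timestamp uniformly over the date window, and its
#' background tokens from a Zipf(1.1) unigram distribution. With probability
#' `mention_rate` the post mentions one drug (uniformly chosen); the mention
#' is misspelled with probability `misspelling_rate` using a variant drawn
#' from the misspelling generator's phonetic stage, and each planted
#' adverse-reaction term for that drug is included adjacent to the mention
#' with its specified co-occurrence probability. Decoy terms appear only in
#' posts without a drug mention. The truth record stores every planted
#' mention, misspelling and co-occurrence, so planted rates can be audited
#' without re-generation.
#'
#' @param spec A [corpus_spec()].
#' @return List with `tweets` (tibble `id`, `created_at`, `text`), `truth`
#'   (tibble `id`, `drug`, `surface`, `misspelled`, `terms` list-column),
#'   and `spec`.
#' @export
generate_corpus <- function(spec) {
  validate_corpus_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_tweets
  bg <- sprintf("w%03d", seq_len(spec$background_vocab))
  bgp <- zipf_probs(spec$background_vocab)
  variant_pool <- lapply(setNames(nm = spec$drugs), function(d) {
    vs <- generate_misspellings(d, oracle = NULL)
    vs$surface[vs$stage2]
  })
  pairs_by_drug <- split(spec$planted_pairs, tolower(spec$planted_pairs$drug))

  lens <- nb_length(n, spec$length_mean, spec$length_dispersion)
  t0 <- as.POSIXct(spec$date_range[1], tz = "UTC")
  t1 <- as.POSIXct(spec$date_range[2], tz = "UTC") + 86399
  stamps <- t0 + runif(n) * as.numeric(difftime(t1, t0, units = "secs"))

  ids <- sprintf("t%06d", seq_len(n))
  texts <- character(n)
  drug_out <- rep(NA_character_, n)
  surface_out <- rep(NA_character_, n)
  miss_out <- rep(NA, n)
  terms_out <- vector("list", n)

  for (i in seq_len(n)) {
    mention <- runif(1) < spec$mention_rate && length(spec$drugs) > 0
    block <- character(0)
    planted <- character(0)
    if (mention) {
      d <- sample(spec$drugs, 1)
      surface <- d
      misspelled <- FALSE
      pool <- variant_pool[[d]]
      if (length(pool) && runif(1) < spec$misspelling_rate) {
        surface <- sample(pool, 1)
        misspelled <- TRUE
      }
      pp <- pairs_by_drug[[d]]
      if (!is.null(pp) && nrow(pp)) {
        fire <- runif(nrow(pp)) < pp$prob
        planted <- pp$term[fire]
      }
      term_toks <- unlist(lapply(planted, preprocess))
      if (length(term_toks)) {
        split_at <- sample.int(length(term_toks) + 1L, 1) - 1L
        block <- c(term_toks[seq_len(split_at)], surface,
                   term_toks[seq_len(length(term_toks) - split_at) + split_at])
      } else {
        block <- surface
      }
      drug_out[i] <- d
      surface_out[i] <- surface
      miss_out[i] <- misspelled
    } else if (length(spec$decoy_terms)) {
      fire <- runif(length(spec$decoy_terms)) < spec$decoy_rate
      planted <- spec$decoy_terms[fire]
      block <- unlist(lapply(planted, preprocess))
    }
    n_bg <- max(0L, lens[i] - length(block))
    bg_toks <- sample(bg, n_bg, replace = TRUE, prob = bgp)
    cut <- sample.int(n_bg + 1L, 1) - 1L
    toks <- c(bg_toks[seq_len(cut)], block,
              bg_toks[seq_len(n_bg - cut) + cut])
    texts[i] <- paste(toks, collapse = " ")
    terms_out[[i]] <- planted
  }

  tweets <- tibble::tibble(id = ids, created_at = stamps, text = texts)
  truth <- tibble::tibble(id = ids, drug = drug_out, surface = surface_out,
                          misspelled = miss_out, terms = terms_out)
  list(tweets = tweets, truth = truth, spec = spec)
}

# Rank layout for the two class vocabularies: class-specific types are
# spread over evenly spaced Zipf ranks (including the top rank) so any
# overlap deficit shows up across the whole frequency spectrum, not only in
# the rare tail.
health_vocab_layout <- function(class_vocab, overlap) {
  m <- class_vocab
  n_specific <- m - round(overlap * m)
  specific_idx <- if (n_specific > 0) {
    unique(round(seq(1, m, length.out = n_specific)))
  } else {
    integer(0)
  }
  # rounding can collapse positions; pad from unused ranks to keep the count
  while (length(specific_idx) < n_specific) {
    specific_idx <- c(specific_idx, setdiff(seq_len(m), specific_idx)[1])
  }
  health <- other <- sprintf("c%03d", seq_len(m))
  health[specific_idx] <- sprintf("h%03d", seq_along(specific_idx))
  other[specific_idx] <- sprintf("o%03d", seq_along(specific_idx))
  list(health = health, other = other)
}

#' Generate a labeled health / non-health corpus
#'
#' Health posts draw content tokens from a health vocabulary and non-health
#' posts from a background vocabulary sharing a fraction `vocab_overlap` of
#' word types (at matched Zipf ranks, so `vocab_overlap = 1` makes the two
#' label-conditional unigram distributions identical by construction and
#' `vocab_overlap = 0` makes the content vocabularies disjoint). The
#' positive fraction follows `health_fraction`. This is the stand-in for a
#' manually annotated health-tweet set with roughly 35% positives.
#'
#' @param spec A [corpus_spec()]; uses `n_tweets`, `health_fraction`,
#'   `vocab_overlap`, `class_vocab`, length and date parameters, and `seed`.
#' @return Tibble `id`, `created_at`, `text`, `label`
#'   (`"health"`/`"non-health"`).
#' @export
generate_health_corpus <- function(spec) {
  validate_corpus_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_tweets
  layout <- health_vocab_layout(spec$class_vocab, spec$vocab_overlap)
  p <- zipf_probs(spec$class_vocab)
  lens <- nb_length(n, spec$length_mean, spec$length_dispersion)
  labels <- ifelse(runif(n) < spec$health_fraction, "health", "non-health")
  t0 <- as.POSIXct(spec$date_range[1], tz = "UTC")
  t1 <- as.POSIXct(spec$date_range[2], tz = "UTC") + 86399
  stamps <- t0 + runif(n) * as.numeric(difftime(t1, t0, units = "secs"))
  texts <- vapply(seq_len(n), function(i) {
    vocab <- if (labels[i] == "health") layout$health else layout$other
    paste(sample(vocab, lens[i], replace = TRUE, prob = p), collapse = " ")
  }, character(1))
  tibble::tibble(id = sprintf("h%06d", seq_len(n)), created_at = stamps,
                 text = texts, label = labels)
}
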