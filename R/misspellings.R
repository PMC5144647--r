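#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' (all unit cost) transforming `a` into `b`, computed with the standard
#' dynamic-programming recurrence. Used as the in-package oracle behind the
#' misspelling-variant generator.
#'
#' @param a,b Character scalars.
#' @return A non-negative integer.
#' @examples
#' levenshtein_distance("kitten", "sitting") # 3
#' @export
levenshtein_distance <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L) return(ny)
  if (ny == 0L) return(nx)
  prev <- 0:ny
  for (i in seq_len(nx)) {
    cur <- c(i, integer(ny))
    for (j in seq_len(ny)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[ny + 1L]
}

#' All spelling variants within one edit of a word
#'
#' Enumerates exactly the strings at Levenshtein distance 1 from `word`:
#' every single-character deletion, every substitution and every insertion,
#' drawing replacement characters from `alphabet` plus the letters of the
#' word itself. The word itself and the empty string are excluded.
#'
#' @param word Lowercase word of at least 2 characters.
#' @param alphabet Character vector of single characters (default `letters`).
#' @return A character vector of unique variants, sorted.
#' @examples
#' v <- levenshtein1_variants("xanax")
#' all(c("xanx", "zanax", "xanaxx") %in% v)
#' @export
levenshtein1_variants <- function(word, alphabet = letters) {
  stopifnot(is.character(word), length(word) == 1L)
  if (nchar(word) < 2L) {
    stop("`word` must have at least 2 characters: ", word, call. = FALSE)
  }
  if (length(alphabet) == 0L) stop("`alphabet` must be non-empty", call. = FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(ch)
  alpha <- unique(c(alphabet, ch))
  dels <- vapply(seq_len(n), function(i) paste(ch[-i], collapse = ""), character(1))
  subs <- unlist(lapply(seq_len(n), function(i) {
    repl <- alpha[alpha != ch[i]]
    vapply(repl, function(a) {
      s <- ch
      s[i] <- a
      paste(s, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }))
  ins <- unlist(lapply(0:n, function(i) {
    vapply(alpha, function(a) {
      paste(c(ch[seq_len(i)], a, ch[seq_len(n - i) + i]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }))
  out <- unique(c(dels, subs, ins))
  sort(out[out != word & nzchar(out)])
}

# Single-character phonetic substitutions of the metaphone-lite encoding.
# Context-sensitive rules (c, digraphs, h) are applied in code.
metaphone_lite_map <- c(q = "k", x = "ks", z = "s", j = "g")

#' Phonetic code of a word (metaphone-lite)
#'
#' A deterministic consonant-skeleton encoding under which homophonous
#' misspellings of a drug name share a code. Rules, applied in order:
#' runs of a repeated letter collapse to one; `ph` becomes `f` and `ck`
#' becomes `k`; `c` becomes `s` before e/i/y and `k` otherwise; `q` becomes
#' `k`, `x` becomes `ks`, `z` becomes `s`, `j` becomes `g`; `h` is dropped
#' unless word-initial; vowels are dropped except a word-initial vowel;
#' repeated-letter runs collapse once more.
#'
#' The encoder used by [phonetic_filter()] and [generate_misspellings()] is
#' pluggable, so a Soundex or Double-Metaphone drop-in with the same
#' signature can replace this default.
#'
#' @param word Non-empty lowercase alphabetic string.
#' @return The code, a character scalar.
#' @examples
#' phonetic_code("adderall") == phonetic_code("adderal") # TRUE
#' phonetic_code("xanax") != phonetic_code("prozac")     # TRUE
#' @export
phonetic_code <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  word <- tolower(word)
  if (!nzchar(word) || grepl("[^a-z]", word)) {
    stop("`word` must be non-empty and alphabetic: ", dQuote(word), call. = FALSE)
  }
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  ch <- ch[c(TRUE, ch[-1] != ch[-length(ch)])]   # collapse runs
  s <- paste(ch, collapse = "")
  s <- gsub("ph", "f", s, fixed = TRUE)
  s <- gsub("ck", "k", s, fixed = TRUE)
  s <- gsub("c(?=[eiy])", "s", s, perl = TRUE)
  s <- gsub("c", "k", s, fixed = TRUE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch <- unlist(lapply(ch, function(x) {
    if (x %in% names(metaphone_lite_map)) {
      strsplit(metaphone_lite_map[[x]], "", fixed = TRUE)[[1]]
    } else {
      x
    }
  }))
  keep <- rep(TRUE, length(ch))
  vowel <- ch %in% c("a", "e", "i", "o", "u")
  keep[vowel] <- FALSE
  keep[ch == "h"] <- FALSE
  keep[1] <- TRUE                                # word-initial kept as-is
  ch <- ch[keep]
  ch <- ch[c(TRUE, ch[-1] != ch[-length(ch)])]
  paste(ch, collapse = "")
}

#' Keep only variants phonetically equal to the source keyword
#'
#' Retains the variants whose phonetic code equals the code of `source`.
#' Variants the encoder cannot process (non-alphabetic) are dropped with a
#' warning rather than failing the whole set.
#'
#' @param variants Character vector of candidate spellings.
#' @param source The canonical keyword.
#' @param encoder Encoding function, by default [phonetic_code()].
#' @return The phonetically equal subset of `variants`.
#' @export
phonetic_filter <- function(variants, source, encoder = phonetic_code) {
  if (length(variants) == 0L) return(character(0))
  target <- encoder(source)
  codes <- vapply(variants, function(v) {
    tryCatch(encoder(v), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(codes)) {
    warning(sum(is.na(codes)), " variant(s) could not be encoded and were dropped",
            call. = FALSE)
  }
  variants[!is.na(codes) & codes == target]
}

#' Build a token-frequency oracle from a reference corpus
#'
#' The third generator step keeps variants that are "in use". The paper-era
#' source of use frequencies (a web search API) is neither stable nor
#' reproducible, so the default oracle counts token occurrences in a
#' user-supplied reference corpus (a tweet tibble from [read_corpus()] /
#' [generate_corpus()], or a list of token vectors).
#'
#' @param corpus A tweet tibble with a `text` column, or a list of
#'   pre-tokenized character vectors.
#' @return A function mapping a character vector of words to their counts.
#' @export
corpus_frequency_oracle <- function(corpus) {
  tokens <- if (is.data.frame(corpus)) {
    unlist(lapply(corpus$text, preprocess))
  } else {
    unlist(corpus)
  }
  tab <- table(tokens)
  counts <- setNames(as.numeric(tab), names(tab))
  function(words) {
    out <- counts[words]
    out[is.na(out)] <- 0
    unname(out)
  }
}

#' Keep variants whose use frequency reaches a threshold
#'
#' @param variants Character vector of candidate spellings.
#' @param oracle A function mapping words to non-negative numbers, or a named
#'   numeric vector (missing names count 0).
#' @param min_count Minimum frequency to survive (default 1: observed at
#'   least once).
#' @return The surviving subset, in input order.
#' @export
frequency_filter <- function(variants, oracle, min_count = 1) {
  if (length(variants) == 0L) return(character(0))
  if (is.numeric(oracle)) {
    counts <- oracle[variants]
    counts[is.na(counts)] <- 0
    counts <- unname(counts)
  } else {
    counts <- vapply(variants, function(v) {
      tryCatch(as.numeric(oracle(v)[1]), error = function(e) NA_real_)
    }, numeric(1), USE.NAMES = FALSE)
    if (anyNA(counts)) {
      warning(sum(is.na(counts)), " variant(s) dropped: frequency oracle failed",
              call. = FALSE)
      counts[is.na(counts)] <- -Inf
    }
  }
  variants[counts >= min_count]
}

#' Generate common phonetically similar misspellings of a drug name
#'
#' The three-step misspelling-variant generator used for recall-oriented
#' keyword collection: (1) enumerate every spelling within one Levenshtein
#' edit of the keyword; (2) keep the candidates whose phonetic code equals
#' the keyword's, so implausible typos are discarded; (3) keep those that a
#' frequency oracle says are actually in use.
#'
#' @param word The correctly spelled keyword (lowercase, alphabetic).
#' @param oracle Frequency oracle for step 3 (see [frequency_filter()]);
#'   `NULL` skips the frequency step, so stage 3 equals stage 2.
#' @param min_count Frequency threshold for step 3.
#' @param alphabet Alphabet for candidate generation.
#' @param encoder Phonetic encoder for step 2.
#' @return A `variant_set`: a tibble with one row per stage-1 variant and
#'   columns `source`, `surface`, `edit` (deletion/substitution/insertion),
#'   `code`, `frequency` (NA when no oracle), and logical `stage1`, `stage2`,
#'   `stage3`.
#' @examples
#' vs <- generate_misspellings("adderall", oracle = NULL)
#' "adderal" %in% vs$surface[vs$stage2]
#' @export
generate_misspellings <- function(word, oracle = NULL, min_count = 1,
                                  alphabet = letters, encoder = phonetic_code) {
  word <- tolower(word)
  stage1 <- levenshtein1_variants(word, alphabet = alphabet)
  stage2 <- phonetic_filter(stage1, word, encoder = encoder)
  freq <- rep(NA_real_, length(stage1))
  if (is.null(oracle)) {
    stage3 <- stage2
  } else {
    stage3 <- frequency_filter(stage2, oracle, min_count = min_count)
    if (is.numeric(oracle)) {
      freq <- unname(ifelse(is.na(oracle[stage1]), 0, oracle[stage1]))
    } else {
      freq <- vapply(stage1, function(v) {
        tryCatch(as.numeric(oracle(v)[1]), error = function(e) NA_real_)
      }, numeric(1), USE.NAMES = FALSE)
    }
  }
  nw <- nchar(word)
  edit <- dplyr::case_when(
    nchar(stage1) < nw ~ "deletion",
    nchar(stage1) == nw ~ "substitution",
    TRUE ~ "insertion"
  )
  codes <- vapply(stage1, function(v) {
    tryCatch(encoder(v), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  in_stage2 <- stage1 %in% stage2
  in_stage3 <- stage1 %in% stage3
  out <- tibble::tibble(
    source = word,
    surface = stage1,
    edit = edit,
    code = codes,
    frequency = freq,
    stage1 = TRUE,
    stage2 = in_stage2,
    stage3 = in_stage3
  )
  class(out) <- c("variant_set", class(out))
  out
}

#' @export
print.variant_set <- function(x, ...) {
  if (all(c("source", "stage1", "stage2", "stage3") %in% names(x))) {
    cat(sprintf(
      "<variant_set> source: %s | stage1: %d, stage2: %d, stage3: %d\n",
      x$source[1], sum(x$stage1), sum(x$stage2), sum(x$stage3)
    ))
  }
  NextMethod()
}
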