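#' Read a tweet-like corpus
#'
#' Reads one post per line from JSONL (objects with keys `id`, `created_at`,
#' `text`) or headerless three-column TSV (`id`, `created_at`, `text`, with
#' literal tabs/newlines in text escaped as `\t` / `\n`). Malformed records
#' — unparseable JSON, missing fields, empty id or text — are skipped; the
#' number skipped is reported via a message and stored in the `skipped`
#' attribute. Timestamps are parsed as ISO-8601 UTC; a record whose
#' timestamp does not parse keeps its text (with `NA` timestamp) and is
#' excluded from monthly statistics with a warning at that point.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` or `"tsv"`.
#' @return A tibble with columns `id`, `created_at` (POSIXct UTC), `text`,
#'   in file order, with attribute `skipped`.
#' @export
read_corpus <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- tibble::tibble(id = character(), created_at = lubridate::ymd_hms(character()),
                          text = character())
    attr(out, "skipped") <- 0L
    return(out)
  }
  recs <- if (format == "jsonl") {
    lapply(lines, function(l) {
      tryCatch({
        o <- jsonlite::fromJSON(l, simplifyVector = TRUE)
        if (!all(c("id", "created_at", "text") %in% names(o))) NULL
        else list(id = as.character(o$id), created_at = as.character(o$created_at),
                  text = as.character(o$text))
      }, error = function(e) NULL)
    })
  } else {
    lapply(lines, function(l) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 3L) return(NULL)
      txt <- gsub("\\t", "\t", gsub("\\n", "\n", parts[3], fixed = TRUE), fixed = TRUE)
      list(id = parts[1], created_at = parts[2], text = txt)
    })
  }
  ok <- !vapply(recs, is.null, logical(1))
  recs <- recs[ok]
  ok2 <- vapply(recs, function(r) nzchar(r$id) && nzchar(r$text), logical(1))
  recs <- recs[ok2]
  skipped <- length(lines) - length(recs)
  if (skipped > 0L) message("read_corpus: skipped ", skipped, " malformed record(s)")
  out <- tibble::tibble(
    id = vapply(recs, `[[`, "", "id"),
    created_at = lubridate::ymd_hms(vapply(recs, `[[`, "", "created_at"),
                                    tz = "UTC", quiet = TRUE),
    text = vapply(recs, `[[`, "", "text")
  )
  attr(out, "skipped") <- skipped
  out
}

#' Write a tweet tibble to JSONL or TSV
#'
#' The inverse of [read_corpus()]; timestamps are written as ISO-8601 UTC.
#'
#' @param tweets Tibble with `id`, `created_at`, `text`.
#' @param path Output path.
#' @param format `"jsonl"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(tweets, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  stamp <- format(tweets$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lines <- if (format == "jsonl") {
    vapply(seq_len(nrow(tweets)), function(i) {
      jsonlite::toJSON(list(id = tweets$id[i], created_at = stamp[i],
                            text = tweets$text[i]), auto_unbox = TRUE)
    }, character(1))
  } else {
    txt <- gsub("\n", "\\n", gsub("\t", "\\t", tweets$text, fixed = TRUE), fixed = TRUE)
    paste(tweets$id, stamp, txt, sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Tokenize raw post text
#'
#' Lowercases, splits on whitespace, then strips leading and trailing
#' punctuation from each token; internal apostrophes and hyphens are kept,
#' and `@`/`#` prefixes are removed with the punctuation (so `#adderall`
#' matches the keyword `adderall`). Empty tokens are dropped. Idempotent on
#' its own output.
#'
#' @param text A character scalar (or vector; tokens are concatenated per
#'   element into a list).
#' @return For a scalar, a character vector of tokens; for a longer vector,
#'   a list of token vectors.
#' @examples
#' preprocess("Just took my Adderall!!")
#' @export
preprocess <- function(text) {
  tok1 <- function(s) {
    toks <- strsplit(tolower(s), "\\s+")[[1]]
    toks <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", toks)
    toks[nzchar(toks)]
  }
  if (length(text) == 0L) return(character(0))
  if (length(text) == 1L) return(tok1(text))
  lapply(text, tok1)
}

#' Match drug keywords in a token sequence
#'
#' A canonical keyword matches iff some token equals the canonical spelling
#' or one of its registered variants — exact token equality, never substring
#' matching, so `adderallfan` does not match `adderall`. Variant hits are
#' credited to their canonical keyword.
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param lexicon A [drug_lexicon()].
#' @return Sorted character vector of matched canonical keywords.
#' @export
match_keywords <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  map <- lexicon_surface_map(lexicon)
  hits <- map[intersect(tokens, names(map))]
  sort(unique(unname(hits)))
}

#' Keep only the posts that mention a drug keyword
#'
#' Retains exactly the tweets whose preprocessed tokens match at least one
#' lexicon keyword, and records the matches in a `keywords` list-column.
#' Idempotent: filtering a filtered corpus changes nothing.
#'
#' @param tweets Tweet tibble (columns `id`, `created_at`, `text`).
#' @param lexicon A [drug_lexicon()].
#' @return The matching subset with a `keywords` list-column added.
#' @export
filter_corpus <- function(tweets, lexicon) {
  kw <- lapply(tweets$text, function(t) match_keywords(preprocess(t), lexicon))
  keep <- lengths(kw) > 0L
  out <- tweets[keep, , drop = FALSE]
  out$keywords <- kw[keep]
  out
}

#' Corpus summary statistics
#'
#' Monthly post counts and per-keyword post counts (a post mentioning a
#' keyword twice still counts once for that keyword), with a top-k keyword
#' table; count ties are broken lexicographically. Posts with unparseable
#' timestamps are excluded from the monthly table with a warning.
#'
#' @param tweets Tweet tibble; a `keywords` list-column is used if present,
#'   otherwise matching is performed against `lexicon`.
#' @param lexicon A [drug_lexicon()].
#' @param k Size of the top-keyword table (default 10).
#' @return A `corpus_stats` object: list of tibbles `monthly` (`year`,
#'   `month`, `n`), `keywords` (`keyword`, `n`) and `top` (the top-k rows).
#' @export
corpus_stats <- function(tweets, lexicon, k = 10) {
  stopifnot(k >= 1)
  if (!"keywords" %in% names(tweets)) tweets <- filter_corpus(tweets, lexicon)
  ok <- !is.na(tweets$created_at)
  if (any(!ok)) {
    warning(sum(!ok), " post(s) without parseable timestamp excluded from monthly counts",
            call. = FALSE)
  }
  monthly <- tweets[ok, , drop = FALSE] |>
    dplyr::mutate(year = lubridate::year(.data$created_at),
                  month = lubridate::month(.data$created_at)) |>
    dplyr::count(.data$year, .data$month, name = "n")
  kws <- unlist(tweets$keywords)
  keywords <- if (length(kws)) {
    tibble::tibble(keyword = kws) |>
      dplyr::count(.data$keyword, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$keyword)
  } else {
    tibble::tibble(keyword = character(), n = integer())
  }
  structure(
    list(monthly = monthly, keywords = keywords,
         top = head(keywords, k), n_tweets = nrow(tweets)),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats> %d post(s), %d month(s), %d keyword(s)\n",
              x$n_tweets, nrow(x$monthly), nrow(x$keywords)))
  if (nrow(x$top)) {
    cat("Top keywords:\n")
    print.data.frame(as.data.frame(x$top), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a corpus_stats object into its keyword table
#'
#' @param x A `corpus_stats` object.
#' @param ... Unused.
#' @return The `keyword`/`n` tibble, ordered by count.
#' @export
tidy.corpus_stats <- function(x, ...) x$keywords

#' Plot corpus statistics
#'
#' Monthly distribution and top-keyword frequency bars.
#'
#' @param object A [corpus_stats()] result.
#' @param ... Unused.
#' @export
autoplot.corpus_stats <- function(object, ...) {
  m <- object$monthly |>
    dplyr::mutate(month_lab = sprintf("%d-%02d", .data$year, .data$month))
  p1 <- ggplot2::ggplot(m, ggplot2::aes(x = .data$month_lab, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "posts", title = "Posts per month")
  p2 <- ggplot2::ggplot(object$top,
                        ggplot2::aes(x = stats::reorder(.data$keyword, .data$n),
                                     y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posts", title = "Top drug keywords")
  list(monthly = p1, keywords = p2)
}
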