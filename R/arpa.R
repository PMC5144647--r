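#' Export an n-gram model to the ARPA text format
#'
#' Writes the standard back-off ARPA file: a `\data\` header with per-order
#' n-gram counts, then one section per order with log10 probability, the
#' n-gram, and (below the top order) the log10 back-off weight. The start
#' marker, which is never a predicted outcome, is written with the
#' conventional placeholder probability -99.
#'
#' @param model An [train_ngram()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_arpa <- function(model, path) {
  stopifnot(inherits(model, "ngram_model"))
  n <- model$n
  sections <- vector("list", n)
  for (k in seq_len(n)) {
    pkeys <- ls(model$prob[[k]])
    bkeys <- if (k < n && !is.null(model$bow[[k]])) ls(model$bow[[k]]) else character(0)
    keys <- sort(union(pkeys, bkeys))
    lp10 <- vapply(keys, function(g) {
      p <- hash_get(model$prob[[k]], g)
      if (is.null(p)) -99 else p / log(10)
    }, numeric(1))
    lines <- if (k < n) {
      b10 <- vapply(keys, function(g) {
        b <- hash_get(model$bow[[k]], g)
        if (is.null(b)) 0 else b / log(10)
      }, numeric(1))
      sprintf("%s\t%s\t%s", format(lp10, digits = 12, trim = TRUE), keys,
              format(b10, digits = 12, trim = TRUE))
    } else {
      sprintf("%s\t%s", format(lp10, digits = 12, trim = TRUE), keys)
    }
    sections[[k]] <- list(count = length(keys), lines = lines)
  }
  out <- c(
    "\\data\\",
    sprintf("ngram %d=%d", seq_len(n), vapply(sections, `[[`, 0L, "count")),
    "",
    unlist(lapply(seq_len(n), function(k) {
      c(sprintf("\\%d-grams:", k), sections[[k]]$lines, "")
    })),
    "\\end\\"
  )
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Import an ARPA-format language model
#'
#' Parses a back-off ARPA file into an `ngram_model` whose
#' [cond_prob()]/[sequence_logprob()] behave identically to the exported
#' model (probabilities preserved to well within 1e-6). Section headers and
#' per-order counts are validated; mismatches raise an error naming the
#' offending line.
#'
#' @param path Path to an ARPA file.
#' @return An `ngram_model` with `smoothing = "arpa"`.
#' @export
import_arpa <- function(path) {
  if (!file.exists(path)) stop("ARPA file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  dstart <- which(trimws(lines) == "\\data\\")
  if (length(dstart) != 1L) stop("ARPA parse error: expected a single \\data\\ header",
                                 call. = FALSE)
  i <- dstart + 1L
  counts <- integer(0)
  while (i <= length(lines) && grepl("^ngram \\d+=\\d+", trimws(lines[i]))) {
    m <- regmatches(trimws(lines[i]), regexec("^ngram (\\d+)=(\\d+)$", trimws(lines[i])))[[1]]
    counts[as.integer(m[2])] <- as.integer(m[3])
    i <- i + 1L
  }
  if (length(counts) == 0L || anyNA(counts)) {
    stop("ARPA parse error at line ", i, ": malformed \\data\\ counts", call. = FALSE)
  }
  n <- length(counts)
  prob <- lapply(seq_len(n), function(k) new_hash())
  bow <- vector("list", n)
  for (k in seq_len(n - 1L)) bow[[k]] <- new_hash()
  for (k in seq_len(n)) {
    hdr <- sprintf("\\%d-grams:", k)
    hi <- which(trimws(lines) == hdr)
    if (length(hi) != 1L) stop("ARPA parse error: missing section header ", hdr,
                               call. = FALSE)
    j <- hi + 1L
    seen <- 0L
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (!nzchar(ln)) { j <- j + 1L; next }
      if (startsWith(ln, "\\")) break
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) parts <- strsplit(ln, " +")[[1]]  # space-delimited fallback
      if (length(parts) < 2L) {
        stop("ARPA parse error at line ", j, ": expected prob<TAB>ngram", call. = FALSE)
      }
      lp10 <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(lp10)) stop("ARPA parse error at line ", j, ": bad probability",
                            call. = FALSE)
      has_bow <- k < n && length(parts) >= 3L &&
        !is.na(suppressWarnings(as.numeric(parts[length(parts)])))
      gram_parts <- if (has_bow) parts[2:(length(parts) - 1L)] else parts[-1L]
      gram <- paste(unlist(strsplit(gram_parts, " +")), collapse = " ")
      ntok <- length(strsplit(gram, " ", fixed = TRUE)[[1]])
      if (ntok != k) stop("ARPA parse error at line ", j, ": ", ntok,
                          "-token gram in ", k, "-gram section", call. = FALSE)
      assign(gram, lp10 * log(10), envir = prob[[k]])
      if (has_bow) {
        assign(gram, as.numeric(parts[length(parts)]) * log(10), envir = bow[[k]])
      }
      seen <- seen + 1L
      j <- j + 1L
    }
    if (seen != counts[k]) {
      stop("ARPA count mismatch for order ", k, ": header says ", counts[k],
           " but section has ", seen, call. = FALSE)
    }
  }
  vocab <- sort(setdiff(ls(prob[[1L]]), NGRAM_BOS))
  structure(
    list(n = n, smoothing = "arpa", discount = NA_real_, min_count = NA_integer_,
         vocab = vocab, prob = prob, bow = bow, counts = NULL),
    class = "ngram_model"
  )
}
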