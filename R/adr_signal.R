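#' Drug-to-term association score
#'
#' Cosine similarity between a drug keyword's vector and an adverse-reaction
#' term. Multi-word terms are scored by the mean cosine over their tokens;
#' tokens missing from the vocabulary are skipped (never zero-filled) and
#' reported through `covered_tokens`. A term whose tokens are all missing
#' cannot be scored and raises an error.
#'
#' @param model An [train_skipgram()] (or loaded) embedding model.
#' @param drug Drug keyword (must be in the vocabulary).
#' @param term Adverse-reaction phrase, e.g. `"dry mouth"`.
#' @return One-row tibble: `drug`, `term`, `score` in [-1, 1],
#'   `covered_tokens`, `total_tokens`.
#' @export
term_similarity <- function(model, drug, term) {
  stopifnot(inherits(model, "embedding_model"))
  dv <- word_vector(model, drug)
  toks <- preprocess(term)
  if (length(toks) == 0L) stop("empty adverse-reaction term", call. = FALSE)
  inv <- toks[toks %in% model$vocab]
  if (length(inv) == 0L) {
    stop("no token of term ", dQuote(term), " is in the vocabulary", call. = FALSE)
  }
  sims <- vapply(inv, function(t) cosine_similarity(dv, word_vector(model, t)),
                 numeric(1))
  tibble::tibble(
    drug = drug, term = term, score = mean(sims),
    covered_tokens = length(inv), total_tokens = length(toks)
  )
}

#' Association profile of a drug over a set of ADR terms
#'
#' One association score per term, in input order — the tabular analogue of
#' a per-drug bar profile of cosine similarities. Terms that cannot be
#' scored (all tokens out of vocabulary) are kept as rows with `NA` score
#' rather than silently dropped or zeroed.
#'
#' @param model An embedding model.
#' @param drug Drug keyword.
#' @param terms Character vector of ADR phrases.
#' @param groups Optional character vector, same length as `terms`, e.g.
#'   `"known"` / `"candidate"`; carried into the result.
#' @return A tibble of class `adr_profile` with columns `drug`, `term`,
#'   `score`, `covered_tokens`, `total_tokens` and optionally `group`.
#' @export
association_profile <- function(model, drug, terms, groups = NULL) {
  stopifnot(length(terms) >= 1L)
  if (!is.null(groups)) stopifnot(length(groups) == length(terms))
  rows <- purrr::map(terms, function(tm) {
    tryCatch(term_similarity(model, drug, tm), error = function(e) {
      tibble::tibble(drug = drug, term = tm, score = NA_real_,
                     covered_tokens = 0L,
                     total_tokens = length(preprocess(tm)))
    })
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(groups)) out$group <- groups
  class(out) <- c("adr_profile", class(out))
  out
}

#' Separation between known and candidate ADR scores
#'
#' Quantifies how cleanly a profile separates the terms known to be
#' associated with the drug from candidate terms: the difference of group
#' mean scores, and the pairwise concordance — the fraction of
#' (known, candidate) pairs in which the known term outscores the candidate,
#' ties counted 1/2. Concordance 1 is perfect separation, 0.5 is chance.
#'
#' @param profile An [association_profile()] result.
#' @param known Character vector of known-ADR terms (subset of the profile).
#' @param candidate Character vector of candidate terms, disjoint from
#'   `known`.
#' @return One-row tibble: `mean_known`, `mean_candidate`, `mean_difference`,
#'   `concordance`, `n_known`, `n_candidate`.
#' @export
separation_statistic <- function(profile, known, candidate) {
  if (length(known) == 0L || length(candidate) == 0L) {
    stop("`known` and `candidate` must both be non-empty", call. = FALSE)
  }
  if (length(intersect(known, candidate))) {
    stop("`known` and `candidate` must be disjoint", call. = FALSE)
  }
  ks <- profile$score[match(known, profile$term)]
  cs <- profile$score[match(candidate, profile$term)]
  if (anyNA(ks) || anyNA(cs)) {
    stop("all known and candidate terms must have scores in the profile",
         call. = FALSE)
  }
  cmp <- outer(ks, cs, `-`)
  concordance <- mean((cmp > 0) + 0.5 * (cmp == 0))
  tibble::tibble(
    mean_known = mean(ks), mean_candidate = mean(cs),
    mean_difference = mean(ks) - mean(cs),
    concordance = concordance,
    n_known = length(ks), n_candidate = length(cs)
  )
}

#' Plot a drug-ADR association profile
#'
#' Bar profile of cosine similarities per term, coloured by group when
#' present.
#'
#' @param object An `adr_profile`.
#' @param ... Unused.
#' @export
autoplot.adr_profile <- function(object, ...) {
  object$term <- factor(object$term, levels = object$term)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$term, y = .data$score))
  p <- if ("group" %in% names(object)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$group))
  } else {
    p + ggplot2::geom_col(fill = "steelblue")
  }
  p + ggplot2::labs(
    x = NULL, y = "cosine similarity",
    title = sprintf("Association signals for %s", object$drug[1])
  ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Read an adverse-reaction term list
#'
#' Plain UTF-8 text, one phrase per line, optional second tab-separated
#' column `known`/`candidate`; `#` comments and blank lines ignored.
#'
#' @param path File path.
#' @return Tibble `term`, `group` (NA when the column is absent).
#' @export
read_adr_terms <- function(path) {
  if (!file.exists(path)) stop("term file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    term = vapply(parts, `[[`, "", 1L),
    group = vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else NA_character_,
                   character(1))
  )
}
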