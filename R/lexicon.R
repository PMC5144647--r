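#' Build a drug keyword lexicon
#'
#' A lexicon pairs canonical drug keywords with their accepted spelling
#' variants; a token matching either form credits the canonical keyword.
#'
#' @param canonical Character vector of keywords (lowercased; must contain no
#'   internal whitespace).
#' @param variants Named list mapping canonical keywords to character vectors
#'   of variant spellings, or a two-column data frame (`canonical`,
#'   `variant`). Every variant must map to exactly one canonical entry.
#' @return A `drug_lexicon` object.
#' @examples
#' lex <- drug_lexicon(c("adderall", "xanax"),
#'                     variants = list(adderall = "adderal"))
#' @export
drug_lexicon <- function(canonical, variants = list()) {
  canonical <- unique(tolower(trimws(canonical)))
  canonical <- canonical[nzchar(canonical)]
  if (any(grepl("\\s", canonical))) {
    stop("canonical keywords must not contain whitespace", call. = FALSE)
  }
  if (is.data.frame(variants)) {
    variants <- split(tolower(variants$variant), tolower(variants$canonical))
  }
  variants <- lapply(variants, function(v) unique(tolower(v)))
  unknown <- setdiff(names(variants), canonical)
  if (length(unknown)) {
    stop("variants given for keywords not in the lexicon: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  map <- unlist(lapply(names(variants), function(k) {
    setNames(rep(k, length(variants[[k]])), variants[[k]])
  }))
  if (anyDuplicated(names(map))) {
    dup <- unique(names(map)[duplicated(names(map))])
    stop("variant(s) mapped to more than one canonical keyword: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(
    list(canonical = canonical, variants = variants, variant_to_canonical = map),
    class = "drug_lexicon"
  )
}

#' Read a lexicon from plain-text files
#'
#' @param path UTF-8 text file, one canonical keyword per line; `#` starts a
#'   comment; blank lines ignored.
#' @param variants_path Optional TSV of `canonical<TAB>variant` pairs, the
#'   format written by the `variants` CLI subcommand.
#' @return A [drug_lexicon()].
#' @export
read_lexicon <- function(path, variants_path = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  canonical <- lines[nzchar(lines)]
  variants <- list()
  if (!is.null(variants_path)) {
    vl <- readLines(variants_path, encoding = "UTF-8", warn = FALSE)
    vl <- vl[nzchar(trimws(vl))]
    parts <- strsplit(vl, "\t", fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad)) stop("malformed variant line(s): ", which(bad)[1], call. = FALSE)
    variants <- data.frame(
      canonical = vapply(parts, `[[`, "", 1L),
      variant = vapply(parts, `[[`, "", 2L)
    )
  }
  drug_lexicon(canonical, variants)
}

#' Attach generated misspelling variants to a lexicon
#'
#' Runs [generate_misspellings()] for each canonical keyword and registers
#' the surviving (stage-3) variants.
#'
#' @param lexicon A [drug_lexicon()].
#' @param oracle,min_count Passed to [generate_misspellings()].
#' @param stage Which generator stage to register (`"stage3"` default).
#' @return The lexicon with variants populated.
#' @export
add_misspellings <- function(lexicon, oracle = NULL, min_count = 1,
                             stage = c("stage3", "stage2")) {
  stage <- match.arg(stage)
  stopifnot(inherits(lexicon, "drug_lexicon"))
  variants <- lapply(setNames(nm = lexicon$canonical), function(k) {
    vs <- generate_misspellings(k, oracle = oracle, min_count = min_count)
    vs$surface[vs[[stage]]]
  })
  drug_lexicon(lexicon$canonical, variants[lengths(variants) > 0])
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat(sprintf("<drug_lexicon> %d keyword(s), %d variant spelling(s)\n",
              length(x$canonical), length(x$variant_to_canonical)))
  invisible(x)
}

# All surfaces (canonical + variants) mapped to their canonical keyword.
lexicon_surface_map <- function(lexicon) {
  c(setNames(lexicon$canonical, lexicon$canonical), lexicon$variant_to_canonical)
}
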