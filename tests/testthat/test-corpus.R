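test_that("JSONL and TSV corpora read in order, skipping malformed records", {
  p <- write_jsonl_fixture(c(
    '{"id":"a","created_at":"2014-11-01T10:00:00Z","text":"hello xanax"}',
    '{"id":"b","created_at":"2014-12-01T10:00:00Z","text":"plain post"}',
    '{"id":"c","created_at":"2015-01-05T10:00:00Z","text":"another"}'
  ))
  tw <- read_corpus(p, "jsonl")
  expect_identical(tw$id, c("a", "b", "c"))
  expect_identical(attr(tw, "skipped"), 0L)
  expect_s3_class(tw$created_at, "POSIXct")

  p2 <- write_jsonl_fixture(c(
    '{"id":"a","created_at":"2014-11-01T10:00:00Z","text":"ok"}',
    'not json at all',
    '{"id":"c","created_at":"2014-11-02T10:00:00Z","text":"ok too"}'
  ))
  expect_message(tw2 <- read_corpus(p2, "jsonl"), "skipped 1")
  expect_identical(nrow(tw2), 2L)
  expect_identical(attr(tw2, "skipped"), 1L)

  p3 <- write_jsonl_fixture(character(0))
  expect_identical(nrow(read_corpus(p3, "jsonl")), 0L)

  p4 <- write_jsonl_fixture(c("x\t2014-11-01T00:00:00Z\ttab\\tinside",
                              "y\t2014-11-02T00:00:00Z\tsecond"),
                            tempfile(fileext = ".tsv"))
  tw4 <- read_corpus(p4, "tsv")
  expect_identical(tw4$text[1], "tab\tinside")
  expect_error(read_corpus(tempfile(), "jsonl"), "not found")
})

test_that("a written corpus round-trips through both dialects", {
  tw <- toy_tweets()
  for (fmt in c("jsonl", "tsv")) {
    f <- tempfile()
    write_corpus(tw, f, fmt)
    back <- read_corpus(f, fmt)
    expect_identical(back$id, tw$id)
    expect_identical(back$text, tw$text)
    expect_equal(as.numeric(back$created_at), as.numeric(tw$created_at))
  }
})

test_that("preprocessing lowercases, strips peripheral punctuation, is idempotent", {
  expect_identical(preprocess("Just took my Adderall!!"),
                   c("just", "took", "my", "adderall"))
  expect_identical(preprocess("XANAX"), "xanax")
  expect_identical(preprocess(""), character(0))
  expect_identical(preprocess("#adderall @user can't re-up"),
                   c("adderall", "user", "can't", "re-up"))
  for (s in c("Hello, WORLD!", "a  b\tc", "#tag... what's—this")) {
    once <- preprocess(s)
    expect_identical(preprocess(paste(once, collapse = " ")), once)
  }
})

test_that("keyword matching is exact-token with variant credit", {
  lex <- drug_lexicon(c("adderall", "xanax"),
                      variants = list(adderall = "adderal"))
  expect_identical(match_keywords(c("took", "adderal"), lex), "adderall")
  expect_identical(match_keywords("adderallfan", lex), character(0))
  expect_identical(match_keywords(c("xanax", "adderall"), lex),
                   c("adderall", "xanax"))
})

test_that("corpus filtering keeps exactly the keyword posts and is idempotent", {
  lex <- drug_lexicon(c("xanax", "adderall"), variants = list(adderall = "adderal"))
  tw <- toy_tweets()
  kept <- filter_corpus(tw, lex)
  expect_identical(kept$id, c("1", "3"))
  expect_identical(kept$keywords[[2]], c("adderall", "xanax"))
  again <- filter_corpus(kept, lex)
  expect_identical(again$id, kept$id)
  expect_identical(again$keywords, kept$keywords)
  none <- filter_corpus(tw[2, ], lex)
  expect_identical(nrow(none), 0L)
})

test_that("filtering a generated corpus recovers the planted mention rate", {
  spec <- corpus_spec(seed = 5, n_tweets = 2000, mention_rate = 0.5,
                      misspelling_rate = 0)
  g <- generate_corpus(spec)
  lex <- drug_lexicon(spec$drugs)
  kept <- filter_corpus(g$tweets, lex)
  expect_lt(abs(nrow(kept) / nrow(g$tweets) - 0.5), 0.05)
})

test_that("corpus statistics count per month and per keyword with stated tie-break", {
  lex <- drug_lexicon(c("a1", "b1", "c1"))
  tw <- tibble::tibble(
    id = as.character(1:3),
    created_at = lubridate::ymd_hms(c("2014-11-03 01:00:00", "2014-11-21 02:00:00",
                                      "2014-12-09 03:00:00"), tz = "UTC"),
    text = c("b1 stuff a1", "a1 again a1", "c1 b1")
  )
  st <- corpus_stats(tw, lex, k = 2)
  expect_identical(st$monthly$n[st$monthly$month == 11], 2L)
  expect_identical(st$monthly$n[st$monthly$month == 12], 1L)
  expect_identical(sum(st$monthly$n), nrow(tw))
  # a1: 2 posts (double mention counts once), b1: 2, c1: 1 -> tie a1 before b1
  expect_identical(st$top$keyword, c("a1", "b1"))
  expect_identical(st$keywords$n[st$keywords$keyword == "a1"], 2L)
  empty <- corpus_stats(tw[0, ], lex, k = 2)
  expect_identical(nrow(empty$monthly), 0L)
  expect_identical(nrow(empty$keywords), 0L)
})

test_that("monthly counts always sum to the filtered corpus size", {
  spec <- corpus_spec(seed = 12, n_tweets = 400)
  g <- generate_corpus(spec)
  lex <- drug_lexicon(spec$drugs)
  kept <- filter_corpus(g$tweets, lex)
  st <- corpus_stats(kept, lex)
  expect_identical(sum(st$monthly$n), nrow(kept))
  months <- sprintf("%d-%02d", st$monthly$year, st$monthly$month)
  expect_true(all(months %in% c("2014-11", "2014-12", "2015-01", "2015-02")))
})
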