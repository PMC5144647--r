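test_that("edit distance matches the classic DP values and an independent oracle", {
  expect_identical(levenshtein_distance("xanax", "xanax"), 0L)
  expect_identical(levenshtein_distance("xanax", "xanx"), 1L)
  expect_identical(levenshtein_distance("kitten", "sitting"), 3L)
  expect_identical(levenshtein_distance("", "abc"), 3L)
  set.seed(11)
  for (i in 1:50) {
    a <- paste(sample(letters[1:6], sample(0:7, 1), TRUE), collapse = "")
    b <- paste(sample(letters[1:6], sample(0:7, 1), TRUE), collapse = "")
    expect_identical(levenshtein_distance(a, b), as.integer(utils::adist(a, b)))
  }
})

test_that("one-edit variant enumeration is exactly the distance-1 set", {
  # frozen from brute-force enumeration over {a,b}, lengths 1..3
  expect_identical(levenshtein1_variants("ab", alphabet = c("a", "b")),
                   sort(c("a", "b", "aa", "bb", "aab", "abb", "aba", "bab")))
  v <- levenshtein1_variants("xanax")
  expect_true(all(c("xanx", "zanax", "xanaxx") %in% v))
  expect_true(all(utils::adist("xanax", v) == 1))
  expect_false("xanax" %in% v)
  expect_error(levenshtein1_variants("a"), "at least 2")
})

test_that("variant enumeration equals brute force on random short words", {
  set.seed(7)
  alpha <- letters[1:4]
  for (i in 1:25) {
    w <- paste(sample(alpha, sample(2:5, 1), TRUE), collapse = "")
    expect_identical(levenshtein1_variants(w, alphabet = alpha),
                     brute_force_variants(w, alpha))
  }
})

test_that("phonetic code is deterministic and separates unlike names", {
  expect_identical(phonetic_code("adderall"), phonetic_code("adderall"))
  expect_identical(phonetic_code("adderall"), phonetic_code("adderal"))
  expect_identical(phonetic_code("seroquel"), phonetic_code("seroquell"))
  expect_false(phonetic_code("xanax") == phonetic_code("prozac"))
  expect_error(phonetic_code("ad3rall"), "alphabetic")
  expect_error(phonetic_code(""), "alphabetic")
})

test_that("phonetic filter keeps homophones, drops unlike variants, is idempotent", {
  kept <- phonetic_filter(c("adderal", "zdderall"), "adderall")
  expect_identical(kept, "adderal")
  expect_identical(phonetic_filter(character(0), "adderall"), character(0))
  v <- levenshtein1_variants("seroquel")
  once <- phonetic_filter(v, "seroquel")
  expect_identical(phonetic_filter(once, "seroquel"), once)
})

test_that("frequency filter applies the threshold rule", {
  counts <- c(adderal = 50, adderakl = 0)
  expect_identical(frequency_filter(c("adderal", "adderakl"), counts, 1), "adderal")
  expect_identical(frequency_filter(c("adderal", "adderakl"), counts, 0),
                   c("adderal", "adderakl"))
  oracle <- corpus_frequency_oracle(list(c("took", "adderal"), c("adderal", "today")))
  expect_identical(frequency_filter(c("adderal", "adderol"), oracle, 2), "adderal")
})

test_that("the three-step generator nests its stages with correct provenance", {
  oracle <- corpus_frequency_oracle(list(c("on", "seroquell", "tonight"),
                                         c("more", "seroquell")))
  vs <- generate_misspellings("seroquel", oracle = oracle, min_count = 1)
  expect_true(all(vs$surface[vs$stage3] %in% vs$surface[vs$stage2]))
  expect_true(all(vs$surface[vs$stage2] %in% vs$surface[vs$stage1]))
  s2 <- vs$surface[vs$stage2]
  expect_true(all(utils::adist("seroquel", s2) == 1))
  expect_true(all(vs$code[vs$stage2] == phonetic_code("seroquel")))
  # the doubled-letter misspelling is common, phonetically equal, and frequent
  expect_true("seroquell" %in% vs$surface[vs$stage3])
  expect_identical(sort(unique(vs$edit)),
                   sort(c("deletion", "substitution", "insertion")))
})

test_that("doubled-letter collapse always survives the phonetic filter", {
  for (w in c("adderall", "seroquel", "wellbutrin", "oxycontin")) {
    ch <- strsplit(w, "", fixed = TRUE)[[1]]
    dbl <- which(ch[-1] == ch[-length(ch)])
    collapsed <- vapply(dbl, function(i) paste(ch[-i], collapse = ""), character(1))
    expanded <- paste(c(ch[seq_len(1)], ch), collapse = "")  # double the first letter
    vs <- generate_misspellings(w, oracle = NULL)
    stage2 <- vs$surface[vs$stage2]
    expect_true(all(collapsed %in% stage2), label = paste("collapse kept for", w))
    expect_true(expanded %in% stage2)
  }
})
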