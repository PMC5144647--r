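---
title: "Mining drug-related chatter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining drug-related chatter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugchatter)
```

## The problem

Public social-media posts are a live, unfiltered record of how people use
prescription drugs: what they take, what it does to them, and how they feel
about it. Mining that record for pharmacovigilance — post-market drug-safety
surveillance — runs into three practical obstacles that this package
addresses end to end:

1. **Collection recall.** Users misspell drug names constantly, so keyword
   collection with only the correct spelling misses a substantial share of
   the relevant chatter. We generate *plausible* misspellings to widen the
   keyword net without flooding it.
2. **Semantic structure.** Associations between a drug and its adverse
   reactions (ADRs) surface as co-occurrence patterns in huge volumes of
   noisy text. Distributed word representations turn those patterns into
   geometry, where a cosine similarity between a drug vector and an ADR-term
   vector is an association signal.
3. **Sequential structure.** Drug chatter is a sub-population of
   health-related text. An n-gram language model trained on it assigns
   higher sequence probabilities to health-related posts than to arbitrary
   ones, which makes the model's score a usable feature for health-text
   classification.

Because the original multi-hundred-thousand-post corpora of this kind are
not redistributable, the package ships a synthetic-corpus generator with the
same statistical skeleton (keyword mentions, misspellings, planted drug–ADR
co-occurrence, heavy-tailed background vocabulary, labeled health/non-health
splits), so every claim the package makes is testable offline.

## Misspelling-variant generation

The generator runs in three stages for a keyword $w$:

1. **Candidates.** Every string at Levenshtein distance exactly 1 from $w$
   — all single-character deletions, substitutions and insertions over the
   alphabet (default a–z). For a length-$m$ word over an alphabet of size
   $A$ this is at most $m + m(A-1) + (m+1)A$ strings before deduplication.
2. **Phonetic filter.** Keep candidates whose phonetic code equals the
   keyword's. The shipped encoder (`phonetic_code()`) is a deliberately
   small, fully documented consonant-skeleton code: collapse repeated-letter
   runs, apply the digraph map (`ph`→`f`, `ck`→`k`), map `c`→`s`/`k` by
   context and `q x z j` to `k ks s g`, drop `h` and non-initial vowels,
   collapse runs again. Homophonous edits — doubled-letter collapses like
   *adderall*→*adderal*, internal vowel swaps like *xanax*→*xanex* —
   survive; phonetically destructive edits such as *xanax*→*zanax* (whose
   skeleton starts `s`, not `ks`) are discarded. The encoder is a
   pluggable argument precisely because the code-equality *contract*, not
   any particular encoding, is what defines the stage.
3. **Frequency filter.** Keep variants that are actually in use. "In use"
   is delegated to a frequency oracle; the default
   (`corpus_frequency_oracle()`) counts token occurrences in a reference
   corpus the caller supplies, which keeps the stage reproducible. The
   threshold `min_count` defaults to 1 — observed at least once.

Stage containment (stage 3 ⊆ stage 2 ⊆ stage 1) and the distance-1 and
code-equality contracts are enforced by construction and re-checked
property-style in the test suite.

## Corpus handling

Posts are read from JSONL or three-column TSV, with malformed records
skipped and counted rather than aborting a large read. Tokenization is
deliberately recall-oriented: lowercase, split on whitespace, strip
peripheral punctuation (so `#adderall` and `Adderall!!` both yield
`adderall`), keep internal apostrophes and hyphens. Keyword matching is
exact-token — substring matching would count `adderallfan` as a mention.
Variant hits credit their canonical keyword, monthly statistics count posts
(not mentions), and ties in the top-keyword table break lexicographically so
outputs are reproducible.

## n-gram language models

For a token sequence $w_1 \dots w_m$ the model factorizes
$P(w_1^m) = \prod_k P(w_k \mid w_{k-n+1}^{k-1})$ with order $n \in \{2,3,4\}$
("tetra-gram" at $n=4$). Sentences are padded with $n-1$ start markers and
one end marker; the end marker and the unknown symbol are first-class
vocabulary members, so each conditional is a proper distribution and
arbitrary text can be scored.

The estimator is **interpolated Kneser–Ney** with a single absolute discount
$D = 0.75$ (configurable): highest-order counts are discounted by $D$ and
the freed mass $D \cdot N_{1+}(c\,\cdot)/c(c)$ is spread over the
lower-order distribution, which itself uses continuation counts
($N_{1+}(\cdot\, g)$, the number of distinct left contexts) rather than raw
counts; the recursion bottoms out in a uniform distribution over the
vocabulary, which also guarantees strictly positive unknown-token mass. With
this construction $\sum_w P(w \mid c) = 1$ holds *algebraically* for every
context, and the suite verifies it to $10^{-6}$ over randomized corpora. An
un-smoothed MLE mode exists purely as a diagnostic whose probabilities are
hand-checkable count ratios.

Models round-trip through the standard ARPA text format (log10
probabilities, per-order sections, back-off weights; the start marker gets
the conventional −99 placeholder), so they interoperate with the wider
n-gram tooling ecosystem.

## Skip-gram embeddings

`train_skipgram()` trains the classic two-layer skip-gram network with
negative sampling: for each input term $t$ the network's parameters $H$ are
fit to raise $P(w \mid t; H)$ for the terms $w$ inside a symmetric context
window. Reference-scale models in this domain use dimensions 200–400 and
windows up to 9; the test suite trains small ($d = 16$) models with the same
code path. Choices worth knowing:

- **Noise distribution** for negative sampling is the unigram distribution
  raised to 0.75, the de-facto standard of this model family.
- **Determinism.** Training is single-threaded, the window is fixed (no
  random shrinking unless `dynamic_window = TRUE`), and all randomness comes
  from one seeded Mersenne–Twister stream whose raw 32-bit outputs are
  mapped to uniforms directly — identical inputs give bitwise-identical
  vectors. Reproducibility outranks speed at desk scale; the inner loop is
  compiled, so desk-scale corpora train in seconds regardless.
- **Exposed representation.** The model's `vectors` are the *sum* of the
  input and context matrices. Input vectors alone encode substitutability
  (paradigmatic similarity); the association signals below need direct
  co-occurrence (syntagmatic) similarity too, and the summed representation
  — the same convention GloVe uses for its final vectors — carries both. On
  synthetic corpora with independent background tokens, a planted
  drug–symptom pair is recovered by the summed vectors across seeds, while
  input-only vectors can even anti-align such a pair. Both component
  matrices remain available on the fitted object.

## Drug–ADR association signals

Given an embedding model, the signal for a (drug, ADR-term) pair is the
cosine similarity of their vectors; a multi-word term scores as the **mean
cosine over its in-vocabulary tokens**. Out-of-vocabulary tokens are skipped
and reported (`covered_tokens`/`total_tokens`) rather than zero-filled —
zero-filling would drag scores toward 0 and fabricate "no signal". A term
with no in-vocabulary token is reported as missing, never as 0. Scores are
deliberately not normalized, rescaled or tuned in any way.

`separation_statistic()` quantifies what a per-drug profile shows visually:
the mean-score gap between terms known to be associated with the drug and
candidate terms, plus the pairwise concordance (fraction of known–candidate
pairs ranked correctly, ties ½). On generator corpora with four terms
planted at 0.8 co-occurrence against six never-co-occurring decoys, the
suite requires concordance ≥ 0.9 in at least 9 of 10 seeds.

## Health-text scoring

A post's raw score is its sequence log-probability under the tetra-gram
model **divided by its transition count**: min–max scaling of raw sums
would mostly rank posts by length, so the per-transition average is the
default (the plain sum is behind a flag). Scores are min–max scaled to
[0, 1] per batch; the map is monotone affine, so rankings are unchanged, and
a degenerate batch (all raw scores equal) maps to 0.5 as the symmetric
choice. Classification thresholds the scaled score; evaluation reports
accuracy/precision/recall/F1 and a threshold-free AUC computed as the
mid-rank Mann–Whitney statistic (ties ½).

## The synthetic-corpus generator

`corpus_spec()` fixes the study conditions; `generate_corpus()` and
`generate_health_corpus()` are deterministic given the spec. Defaults encode
the conditions the package is tested under:

| Parameter | Default | Why |
|---|---|---|
| `date_range` | 2014-11-01 – 2015-02-28 | the four-month collection window this corpus family uses |
| `mention_rate` | 0.5 | half the simulated stream mentions a drug, so filtering is non-trivial both ways |
| `misspelling_rate` | 0.1 | a realistic minority of mentions misspelled; variants drawn from the generator's phonetic stage, so planted misspellings are homophonous by construction |
| `length_mean` / `length_dispersion` | 12 / 5 | negative-binomial tweet-scale lengths |
| `background_vocab`, Zipf exponent | 500, 1.1 | heavy-tailed token frequencies typical of user-generated text |
| `health_fraction` | 0.35 | matches the roughly one-third-positive composition of the reference labeled health-tweet sets |
| `vocab_overlap` | 0.8 | health and non-health share most of their vocabulary; 1 is the no-signal control, 0 the trivially separable extreme |

Planted ADR terms are placed *adjacent* to the drug mention (split around
it), because window-based co-occurrence is the mechanism under test; decoy
terms appear only in posts without a drug mention. Class-specific vocabulary
in the health corpus occupies evenly spaced Zipf ranks, so the overlap
parameter thins the signal across the whole frequency spectrum instead of
hiding it in the rare tail. The truth record carries every planted mention,
misspelling and co-occurrence, so generator calibration (recovered rates
within ±0.04 at n = 2000, label fraction within ±0.05 at n = 1000) is
audited without regeneration.

What the generator does **not** emulate: real orthographic variation beyond
one edit, topical drift, duplicate/retweet structure, multilingual text,
named entities, and any dependence between background tokens. Passing tests
therefore demonstrate that the implementations are correct and that the
pipeline recovers planted structure under realistic noise levels — not that
the signals reach any particular strength on live social-media data.

## Numerical and design notes

- Discount $D = 0.75$; counts below `min_count` pool into the unknown
  symbol; ARPA files print log10 values at 12 significant digits, making
  round-trips identity to well below the 1e-6 contract.
- Cosine similarity clamps to $[-1, 1]$ against floating-point drift and
  refuses zero vectors rather than returning NaN.
- Top-k and nearest-neighbour lists break score ties lexicographically.
- Posts with unparseable timestamps keep their text but are excluded (with
  a warning) from monthly statistics.
- Problem sizes used by the test and acceptance runs — 2,000-post corpora
  for association recovery, 1,500/1,000-post train/evaluation splits for
  health scoring, 50 randomized small corpora for normalization, 200 random
  words for the edit-distance oracle — were chosen as the smallest sizes at
  which the planted effects are comfortably above sampling noise.

## Limitations

- The phonetic encoder is intentionally minimal; it is a filter contract,
  not a pronunciation model, and will both pass some implausible variants
  and drop some plausible ones. Swap in a richer encoder via the `encoder`
  argument where that matters.
- One-edit variants only: real misspellings include keyboard slips,
  split/merge errors and distance-2 edits, which are out of scope here.
- The embedding trainer is deliberately single-threaded; it is not meant
  for hundred-million-token corpora.
- Association signals are similarities, not disproportionality statistics;
  they rank hypotheses and do not test them.
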