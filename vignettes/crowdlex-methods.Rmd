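---
title: "Methods: dictionary-based classification of medical crowdfunding campaigns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary-based classification of medical crowdfunding campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdlex)
```

## The model

`crowdlex` classifies free-text crowdfunding campaigns into two binary
categories — *cancer-related* and *benefitting an LGBTQ+ individual* —
by surface-term matching against curated lexicons, deliberately without
machine learning. For a stigmatized population, a trained classifier
inherits whatever biases sit in its training signal and cannot be
audited term by term; a lexicon can. The cost of that choice is that
the lexicon itself must be refined against human judgement, which is
why the package treats the *refinement workflow* — quality-check
routing, per-term misclassification attribution, pairwise agreement
against a gold-standard coder — as part of the model rather than an
afterthought.

Each lexicon entry has a **match type** and a **lifecycle status**. The
match types define the only five matching semantics the package
supports:

| match type | rule | example |
|---|---|---|
| `whole_word` | surface equals one maximal token | "queer" |
| `prefix_stem` | surface is a leading substring of a token | "malignan" → *malignancy* |
| `phrase` | consecutive tokens equal the surface's tokens | "her wife" |
| `phrase_prefix` | phrase whose last token is a prefix match | "bottom surg" → *bottom surgery* |
| `pronoun_slash` | token immediately followed by `/` | "they/" → *they/them* |

Statuses encode the refinement history: `active` terms classify;
`quality_check` terms match but route the campaign to manual review;
`eliminated` and `zero_hit` terms compile to nothing and exist for
auditability. The packaged files ship the initial and final iterations
of both lexicons; `diff_dictionaries()` recovers the refinement between
any two iterations and `apply_dictionary_diff()` replays it.

## Tokenization and matching semantics

Tokens are maximal runs of Unicode letters, digits, and ASCII
apostrophes. Three consequences are load-bearing:

* **Hyphens are boundaries.** "trans-metatarsal" tokenizes to
  `trans`, `metatarsal`, so the ambiguous term "trans" *does* hit
  hyphenated medical compounds. This is intentional: those hits are the
  documented false-positive mode, and the quality-check status — not
  the tokenizer — is the mechanism that keeps them out of automatic
  positives. A tokenizer that kept hyphenated compounds whole would
  silently hide the ambiguity instead of surfacing it for review.
* **Apostrophes are token-internal**, because the cancer lexicon
  contains "wilm's tumor". Typographic (curly) apostrophes are not
  folded to ASCII; a corpus using them would need normalization
  upstream, and that limitation is deliberate (no silent text
  rewriting).
* **No diacritic folding.** The cancer lexicon lists the Spanish
  "cáncer" but, notably, not the bare English "cancer"; folding
  accents would effectively add a term the curated list does not
  contain and change corpus selection silently. So "cáncer" matches
  only the accented form and plain "cancer" matches nothing. A study
  wanting the unaccented word adds it to a dictionary file explicitly.

Matching is case-insensitive (via locale-independent lower-casing;
surfaces are stored as curated, since list capitalization is
editorial). A surface ending in `"."` ("Mx.") requires the token to be
followed by a literal period — the period is what distinguishes the
honorific from stray "mx" strings — and `pronoun_slash` surfaces
require a following `/`, so "they/them" hits while a bare "they"
does not.

Hit spans are half-open character intervals into the searched text,
which is the title and description joined by a paragraph break (the
break is a token boundary, so no term can straddle the seam; the
result records where the description begins). Searching both fields is
the inclusive choice; the field set is a parameter.

The three-state classification is then a pure function of the hits: any
active hit ⇒ `positive`; otherwise any hit ⇒ `qc_pending`; otherwise
`negative`. Quality-check resolutions (`confirm`/`reject`) are applied
afterwards and only to pending results, mirroring a workflow where
ambiguous hits are always human-reviewed. The study subset is the
conjunction of cancer-positive and LGBTQ+-positive; unresolved
`qc_pending` is excluded by default (conservative: an unreviewed
ambiguous hit never enters the study) and includable for sensitivity
analysis.

The matcher's correctness is established against an independent
brute-force scanner implemented in the test suite with different
machinery (character-walking tokenizer, per-position term-by-term
scanning); the two must agree exactly on a thousand randomized texts
mixing true terms, inflections, near misses, and the documented
confounders.

## Language handling

The corpus rule is: keep a campaign if and only if English is among its
detected languages, so campaigns written in English *plus* another
language are retained. A whole-document detector cannot implement this
rule — it reports the majority language — so `detect_language()` splits
the text into paragraphs, detects each, and unions the codes.

Detection itself is an injectable interface. The packaged default is a
deterministic stop-word-profile scorer over English, Spanish, French,
and German: each paragraph is scored by the fraction of its tokens
found in a curated function-word list per language, with a minimum
score of 0.1 (below it the paragraph is `und`). Two properties drove
this design: determinism (statistical detectors are seed- and
version-sensitive, and a reproducible pipeline should not flake on its
language calls) and auditable failure modes. The profiles contain only
function words, never content words, so language detection cannot
interact with term matching. The trade-off is breadth: texts in
unprofiled languages come back `und` and are excluded — which is the
correct action under the English-retention rule — and very short
mixed-language fragments inside a single paragraph are attributed to
one language. Any function mapping a paragraph to a code can be
plugged in instead.

## US-location rule

Campaign pages give organizer locations as free text, and the corpus
filter needs a deterministic, auditable "US" predicate. The rule:
split on commas and accept if any component is a US state/territory
name, the District of Columbia, a USPS two-letter abbreviation
(matched upper-case only, so function words like Spanish "de" can
never trip it), or a country token ("USA", "United States", …). This
misses locations given as bare city names, and that is accepted: a
false exclusion is auditable from the stored location string, whereas
a fuzzy geocoder would not be reproducible offline.

## Percent agreement and its arithmetic

Agreement between two coders (one of which may be the term list) is
simple proportion agreement, `100 × n_agree / n`, reported to one
decimal with **half-up rounding** — `round_half_up()` exists because
R's `round()` rounds half to even, and reported percentages in this
workflow follow the half-up convention. Chance-corrected kappa is
computed as a clearly-labelled extra field, never as the headline
number. The test suite verifies the printed-precision behaviour by
exhaustive search: for each (n, percentage) pair the workflow reports,
exactly one integer agreement count in 0..n reproduces the printed
percentage, and the package's report yields it.

Misclassification attribution counts, for each term, the false-positive
campaigns (dictionary-positive, gold "no") whose hits include that
term. A campaign with k distinct hitting terms contributes to all k
rows — so the column sums to at least the number of false-positive
campaigns, with equality exactly when every false positive has a single
hitting term. This over-counting is documented rather than "fixed"
because the table's purpose is to rank candidate terms for
elimination, and a term is implicated whenever it co-occurs with a
misclassification.

## The synthetic corpus generator

The generator exists so that every pipeline stage — scraping, language
filtering, corpus filtering, matching, classification, evaluation —
can be exercised against known ground truth without any network
access. It emulates:

* true cancer campaigns (≥1 final-list cancer term planted, across
  match types: whole words, the "malignan" stem, multi-token phrases,
  "wilm's tumor");
* true LGBTQ+ disclosures within cancer campaigns (≥1 active final-list
  term across all five match types; the pronoun-type plant uses
  "ne/nem", the pronoun-slash entry of the final lexicon);
* the documented confounders: medical "trans-" compounds, "Gay" as a
  legal name, treatment words used for non-cancer disease, tangential
  mentions of a family member's cancer, fully non-English and
  mixed-language descriptions — plus benign uses of the
  later-eliminated terms ("partner", "fluid", "transitioning"), which
  are what make refinement measurable on synthetic data;
* metadata variation (category, status, US and non-US locations,
  missing optional fields) so the corpus filter has genuine work.

Text is hand-written English crowdfunding-style sentences with slot
filling — no generative model — for determinism and license
cleanliness, and every non-planted sentence is vetted to contain no
term from either lexicon iteration, so planted content alone determines
match output. Confounders are planted only in campaigns whose truth
flag for the corresponding dictionary is negative ("confounded
campaigns embed only the confounder pattern"), which gives the
generator's plant log exact oracle status for precision/recall and
attribution tests.

**Default parameters.** `n_campaigns = 500`; `p_cancer = 0.25`;
`p_lgbtq_given_cancer = 0.2`; each confounder rate `0.05`;
`field_missingness = 0.05`. These are desk-scale conditions chosen once
for coverage: in a production crowdfunding corpus, cancer campaigns are
a few percent of medical campaigns and disclosed-LGBTQ+ cancer
campaigns are well under one percent, rates at which a 500-campaign
corpus would contain almost no positive examples and a test suite would
assert on noise. The elevated rates keep every branch (true positives,
each confounder, each filter) populated at sizes a laptop runs in
seconds. The consequence, stated plainly: agreement percentages
computed on these synthetic corpora reflect the configured
confounder-to-signal ratio, not any real corpus's, and are reported as
properties of the synthetic conditions (what refinement *does* to
them), never as estimates of real-world accuracy. Passing tests show
the machinery is correct under planted truth; they do not show that
the lexicons generalize to text the generator does not emulate
(sarcasm, misspellings beyond the curated variants, rich narrative
structure, non-Spanish second languages).

## Numerical and degenerate-input choices

* Rounding: half-up at one decimal everywhere a percentage is
  reported; comparisons in tests use exact fractions where possible.
* Empty text, empty corpora, empty `urlset`s, and zero-item coding
  sets are all defined (negative classification, all-terms zero-hit
  audit, empty URL list, `NA` agreement) rather than errors.
* Ties in language scoring break on the fixed profile order; ties in
  attribution ranking break alphabetically — both deterministic.
* Sitemap indexes flatten exactly one level; deeper nesting is an
  error rather than unbounded recursion.
* Record serialization is strict: ISO-8601 dates only, unknown JSONL
  keys rejected, negative counts rejected with the row named. Blank
  JSONL lines are skipped with a logged count (a concession to
  hand-edited files; everything else is rejected loudly).

## Dictionary transcription decisions

The packaged files transcribe their curated source lists entry by entry, with
three documented judgement calls. (1) The final LGBTQ+ file carries
"Trans" with `quality_check` status even though the source final
list omits it: the source quality-check list names "Gay" and
"Trans", and the documented behaviour — medical "trans-" compounds
routed to review — requires the term to keep matching. (2) Two initial
cancer entries appear run together in the source ("non hodgkins
lymphoma nonhodgkins lymphoma", "rhabdomyosarcoma rhabdomyosaroma") and
are transcribed verbatim with a flagging comment; the final file prints
them as separate terms. (3) Match types are fixed in the files since
the source prints bare strings: truncated stems are `prefix_stem`,
multiword entries ending in truncations are `phrase_prefix`, entries
ending in `/` are `pronoun_slash`, other multiword (or hyphenated)
entries are `phrase`, and everything else is `whole_word` — the
assignment that reproduces the documented behaviours (stems hitting
inflections, "trans" hitting hyphenated compounds).

## Problem sizes

The shipped tests run the matcher-oracle comparison on 1,000 randomized
texts, planted-label recovery through the full pipeline at 500
campaigns, refinement and attribution checks at 250–300 campaigns, and
`scripts/acceptance.R` uses 500 (clean pipeline) and 2,000 (confounded
corpus) campaigns. These sizes were chosen so the whole suite completes
in about two minutes on one core while every statistic it asserts on
has a comfortably non-degenerate sample behind it.

## Known limitations

* The fixture HTML template is this package's own; real platform markup
  (and live crawling generally) is out of scope by design.
* The lexicons are specific to the corpus and era they were refined
  against; applying them elsewhere without re-auditing zero-hit and
  quality-check behaviour would be a methodological error, and the
  audit tools exist precisely to make that re-auditing cheap.
* Identity identification is via self-disclosure only. The package
  measures what is disclosed, which undercounts the population and is
  the ethically appropriate floor for this kind of analysis.
* The stop-word language detector covers four languages; descriptions
  in other languages are excluded as undetermined rather than
  misclassified, but their English-mixed variants may lose the second
  language's code.
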