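# crowdlex

Dictionary-based identification of cancer-related crowdfunding campaigns
that benefit LGBTQ+ individuals.

## The problem

Sexual orientation and gender identity are rarely recorded in the data
sources used to study cancer-related financial burden, so inequities
affecting LGBTQ+ cancer survivors are hard to measure directly. Online
crowdfunding campaigns are one place where identity *is* often disclosed
— through gendered language ("her wife", "they/them") and explicit
self-description — alongside a free-text account of the medical
situation. `crowdlex` implements the classification machinery for
mining such corpora without machine learning (which risks infusing
researcher bias into the identification of a stigmatized population):

* **Curated term dictionaries** for LGBTQ+ identity disclosure and for
  cancer, shipped in their initial and final refinement iterations, with
  explicit per-term match semantics (`whole_word`, `prefix_stem`,
  `phrase`, `phrase_prefix`, `pronoun_slash`) and lifecycle status
  (`active`, `quality_check`, `eliminated`, `zero_hit`).
* **A three-state classifier**: a campaign is `positive` when an active
  term hits, `qc_pending` when only ambiguous quality-check terms hit
  (e.g. "trans" inside *trans-metatarsal*, or "Gay" as a legal name) —
  routed to manual review, never auto-classified — and `negative`
  otherwise. Every classification carries full term-hit provenance
  (term, match type, character span).
* **Corpus ingestion**: sitemap parsing, static-HTML field extraction
  (eight fields: title, creation date, category, status, donation
  amount, donor count, organizer location, description), JSONL/CSV
  record I/O, language detection with an English-retention rule
  (bilingual English+other campaigns are retained), and the
  active/US/medical corpus filter.
* **Evaluation against manual coding**: random coding samples, pairwise
  percent agreement (`100 × n_agree / n`, rounded half-up to one
  decimal) against a designated gold-standard coder, and per-term
  misclassification attribution — the audit that identifies which
  lexicon entries drive false positives across refinement iterations.
* **A synthetic corpus generator** with planted ground truth (true
  disclosures, true cancer content, and the documented confounder
  patterns), so the entire pipeline is testable end to end without any
  scraping.

Live web crawling is out of scope: ingestion operates on sitemap + HTML
fixtures in the repository's own page template, or on record files.

## Worked example

```r
library(crowdlex)

# a synthetic corpus with planted truth, emitted as a fixture site
corpus <- generate_corpus(synthetic_config(n_campaigns = 200, seed = 42))
emit_fixture_site(corpus$records, "site")

run <- run_pipeline(pipeline_config(input = "site", out_dir = "out", seed = 42))
#> ingest: 200 record(s)
#> english retention: 192 record(s)
#> active US medical in English: 101 record(s)
#> cancer: 33 positive, 0 qc_pending, 68 negative
#> lgbtq: 5 positive, 12 qc_pending, 84 negative
#> study subset: 5 campaign(s); 5 excluded only by unresolved quality checks
#> LGBTQ+ cancer study subset: 5 campaign(s)
```

The funnel lines mirror the pipeline stages: 200 generated campaigns,
192 with English descriptions, 101 surviving the active/US/medical
filter, and the study subset is the conjunction of cancer-positive and
LGBTQ+-positive classifications (campaigns whose only LGBTQ+ signal is
an unresolved quality-check hit are excluded under the default policy —
here 5 further campaigns, pending manual review).

Individual classifications retain full provenance:

```r
lg <- compile_matcher(load_dictionary(crowdlex_dictionary("lgbtq", "final")))
match_text(lg, "She underwent a trans-metatarsal amputation; her wife was there.")
#> # A tibble: 2 × 5
#>   surface  match_type status        start   end
#>   <chr>    <chr>      <chr>         <int> <int>
#> 1 Trans    whole_word quality_check    17    22
#> 2 Her wife phrase     active           46    54
```

The hyphenated medical compound hits only the quality-check term
("trans"), so alone it would leave the campaign `qc_pending`; the
phrase "her wife" is an active term and classifies the campaign
LGBTQ+-positive outright.

Agreement evaluation follows the coding workflow:

```r
ids <- sprintf("c%02d", 1:93)
term_list <- coding_records(ids, "term_list", rep("yes", 93))
sab <- coding_records(ids, "sab", c(rep("yes", 82), rep("no", 11)))
pairwise_agreement(term_list, sab)
#> <agreement report: 82/93 items agree, 88.2% agreement, 11.8% misclassification>
```

## Command line

A thin CLI over the same functions ships in `inst/cli/crowdlex.R`
(subcommands `simulate`, `scrape`, `classify`, `evaluate`,
`diff-dicts`, `audit-zero-hits`, `run`). The methods vignette
(`vignettes/crowdlex-methods.Rmd`) documents the model, the match
semantics, the generator, and the package's design decisions.
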