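Package: crowdlex
Title: Dictionary-Based Classification of Medical Crowdfunding Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying cancer-related crowdfunding campaigns that
    benefit LGBTQ+ individuals from web-scraped campaign corpora. Provides
    curated, versioned term dictionaries (LGBTQ+ identity disclosure and
    cancer) with explicit match semantics and a quality-check workflow for
    ambiguous terms, sitemap and static-HTML campaign ingestion, language
    detection and English-retention filtering, three-state dictionary
    classification with full term-hit provenance, pairwise percent-agreement
    evaluation against manual coding with per-term misclassification
    attribution, and a synthetic campaign-corpus generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
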